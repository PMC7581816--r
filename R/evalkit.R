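#' Prediction error rate
#'
#' `100 * mismatched steps / total steps`, pooled over all sequences
#' (micro-average at the time-step level).
#'
#' @param y_true,y_pred integer label vectors, or lists of aligned vectors.
#' @return Percentage in `[0, 100]`.
#' @export
#' @examples
#' per(c(1, 2, 1, 2), c(1, 2, 2, 2))  # 25
per <- function(y_true, y_pred) {
  if (is.list(y_true) != is.list(y_pred))
    stop("y_true and y_pred must both be vectors or both be lists",
         call. = FALSE)
  if (!is.list(y_true)) {
    y_true <- list(y_true); y_pred <- list(y_pred)
  }
  if (length(y_true) != length(y_pred))
    stop("different numbers of sequences", call. = FALSE)
  wrong <- 0L; total <- 0L
  for (i in seq_along(y_true)) {
    a <- as.integer(y_true[[i]]); b <- as.integer(y_pred[[i]])
    if (length(a) != length(b))
      stop("sequence ", i, ": lengths ", length(a), " and ", length(b),
           " differ", call. = FALSE)
    wrong <- wrong + sum(a != b)
    total <- total + length(a)
  }
  if (total == 0L) stop("no steps to score", call. = FALSE)
  100 * wrong / total
}

#' Confusion matrix over labels
#'
#' @param y_true,y_pred integer label vectors or lists of them.
#' @param L number of labels.
#' @param labels optional label names for dimnames.
#' @return L x L integer count matrix, rows = true label.  The pooled PER
#'   equals `100 * (1 - sum(diag(m)) / sum(m))` exactly.
#' @export
confusion_matrix <- function(y_true, y_pred, L, labels = NULL) {
  if (!is.list(y_true)) { y_true <- list(y_true); y_pred <- list(y_pred) }
  dn <- if (is.null(labels)) list(true = seq_len(L), pred = seq_len(L))
        else list(true = labels, pred = labels)
  m <- matrix(0L, L, L, dimnames = dn)
  for (i in seq_along(y_true)) {
    a <- as.integer(y_true[[i]]); b <- as.integer(y_pred[[i]])
    if (length(a) != length(b))
      stop("sequence ", i, ": lengths differ", call. = FALSE)
    for (t in seq_along(a)) m[a[t], b[t]] <- m[a[t], b[t]] + 1L
  }
  m
}

#' Memoryless softmax baseline
#'
#' A single affine + softmax layer on the present feature vector, trained by
#' the same mini-batch SGD with momentum as the TDNN stage.  It ignores all
#' temporal context, so it serves as the comparator that isolates what the
#' prior-state window contributes.
#'
#' @param data a fully labeled [sequence_set()].
#' @param control a [tdnn_control()] (batch size, learning rate, momentum,
#'   epochs, seed).
#' @return An object of class `memoryless` with `W` (D x L), `b`, the label
#'   alphabet and the per-epoch loss trace.
#' @export
memoryless_fit <- function(data, control = tdnn_control()) {
  stopifnot(inherits(data, "sequence_set"))
  Fmat <- do.call(rbind, lapply(data$sequences, `[[`, "f"))
  y <- unlist(lapply(data$sequences, `[[`, "y"))
  if (anyNA(y)) stop("baseline training needs full labels", call. = FALSE)
  L <- length(data$alphabet)
  n <- length(y); D <- ncol(Fmat)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(control$seed)
  W <- matrix(stats::rnorm(D * L, sd = 0.01), D, L)
  b <- numeric(L)
  vW <- 0 * W; vb <- 0 * b
  trace <- numeric(control$epochs)
  for (ep in seq_len(control$epochs)) {
    ord <- sample.int(n)
    starts <- seq(1L, n, by = control$batch_size)
    losses <- numeric(length(starts))
    for (bi in seq_along(starts)) {
      idx <- ord[starts[bi]:min(starts[bi] + control$batch_size - 1L, n)]
      X <- Fmat[idx, , drop = FALSE]
      p <- .softmax_rows(sweep(X %*% W, 2L, b, `+`))
      losses[bi] <- -mean(log(pmax(p[cbind(seq_along(idx), y[idx])],
                                   1e-300)))
      dlog <- p
      dlog[cbind(seq_along(idx), y[idx])] <-
        dlog[cbind(seq_along(idx), y[idx])] - 1
      dlog <- dlog / length(idx)
      if (control$lr > 0) {
        vW <- control$momentum * vW - control$lr * crossprod(X, dlog)
        vb <- control$momentum * vb - control$lr * colSums(dlog)
        W <- W + vW; b <- b + vb
      }
    }
    trace[ep] <- mean(losses)
  }
  structure(list(W = W, b = b, alphabet = data$alphabet,
                 loss_trace = trace, control = control),
            class = "memoryless")
}

#' @export
predict.memoryless <- function(object, newdata, ...) {
  f <- if (inherits(newdata, "sequence_set")) {
    lapply(newdata$sequences, `[[`, "f")
  } else list(newdata)
  out <- lapply(f, function(X) {
    p <- .softmax_rows(sweep(X %*% object$W, 2L, object$b, `+`))
    list(labels = apply(p, 1L, which.max), posterior = p)
  })
  if (length(out) == 1L && !inherits(newdata, "sequence_set"))
    return(out[[1]])
  names(out) <- vapply(newdata$sequences, `[[`, character(1), "id")
  out
}

#' Evaluate the memoryless baseline
#'
#' @param model a fitted `memoryless` classifier.
#' @param data a fully labeled [sequence_set()].
#' @return PER percent (pooled).
#' @export
evaluate_memoryless <- function(model, data) {
  preds <- predict(model, data)
  per(lapply(data$sequences, `[[`, "y"),
      lapply(preds, `[[`, "labels"))
}

#' Hidden-state-count ablation
#'
#' Trains and evaluates one DTMN per hidden-state count, repeating with
#' seeds `seed, seed + 1, ...` and a fresh per-repeat holdout split, and
#' reports the PER per setting — the sweep over HMM capacity.
#'
#' @param data a labeled [sequence_set()].
#' @param Ns integer vector of hidden-state counts.
#' @param repeats independent repeats per setting (default 5).
#' @param seed base seed.
#' @param context,hidden_dim,control,hmm_max_iter forwarded to [dtmn()].
#' @param holdout held-out sequence fraction (default 0.2).
#' @return An object of class `dtmn_ablation`: a data frame with columns
#'   `setting`, `rep`, `seed`, `per`, plus a `summary` attribute of mean/sd
#'   per setting.
#' @export
ablate_hidden_states <- function(data, Ns, repeats = 5L, seed = 1L,
                                 context = "tdnn4", hidden_dim = 64L,
                                 control = tdnn_control(),
                                 hmm_max_iter = 100L, holdout = 0.2) {
  if (length(Ns) == 0L) stop("Ns is empty", call. = FALSE)
  if (repeats < 1L) stop("repeats must be >= 1", call. = FALSE)
  rows <- list()
  for (r in seq_len(repeats)) {
    s <- seed + r - 1L
    sp <- split_holdout(data, holdout, seed = s)
    for (N in Ns) {
      model <- tryCatch(
        dtmn(sp$train, n_hidden = N, context = context,
             hidden_dim = hidden_dim, control = control,
             hmm_max_iter = hmm_max_iter, seed = s),
        error = function(e)
          stop("ablation run failed at N = ", N, ", repeat ", r, ": ",
               conditionMessage(e), call. = FALSE))
      ev <- evaluate_model(model, sp$test)
      rows[[length(rows) + 1L]] <-
        data.frame(setting = N, rep = r, seed = s, per = ev$per,
                   hmm_loglik = model$hmm_trace[length(model$hmm_trace)])
    }
  }
  .ablation_result(do.call(rbind, rows), "n_hidden")
}

#' Temporal-context ablation
#'
#' Compares the named TDNN context presets while sharing the HMM stage
#' within each repeat: the HMM is fitted and posterior-decoded once per
#' repeat, then only the TDNN is retrained per variant, isolating the
#' context factor.
#'
#' @param data a labeled [sequence_set()].
#' @param variants character vector of context preset names
#'   (default all of `tdnn1` .. `tdnn6`).
#' @param repeats,seed,holdout as in [ablate_hidden_states()].
#' @param n_hidden HMM hidden-state count (default 10).
#' @param hidden_dim,control,hmm_max_iter forwarded to the stages.
#' @param refine_rounds rollout refinement rounds per variant, as in
#'   [dtmn()] (default 2).
#' @return A `dtmn_ablation` data frame keyed by preset name.
#' @export
ablate_contexts <- function(data, variants = paste0("tdnn", 1:6),
                            repeats = 5L, seed = 1L, n_hidden = 10L,
                            hidden_dim = 64L, control = tdnn_control(),
                            hmm_max_iter = 100L, holdout = 0.2,
                            refine_rounds = 2L) {
  ctxs <- lapply(variants, tdnn_context)   # validates names up front
  rows <- list()
  for (r in seq_len(repeats)) {
    s <- seed + r - 1L
    sp <- split_holdout(data, holdout, seed = s)
    ys <- label_sequences(sp$train)
    L <- length(data$alphabet)
    hmm0 <- hmm_init(n_hidden, L, seed = s)
    fit <- hmm_fit(hmm0, ys, max_iter = hmm_max_iter)
    paths <- lapply(ys, function(y) hmm_decode(fit$params, y))
    flist <- lapply(sp$train$sequences, `[[`, "f")
    for (v in seq_along(variants)) {
      ctx <- ctxs[[v]]
      ex <- .build_examples(paths, sp$train, ctx)
      ctrl <- control; ctrl$seed <- s
      net <- tdnn_fit(ex, ctx, n_states = fit$params$N, control = ctrl,
                      hidden_dim = hidden_dim)
      for (r2 in seq_len(refine_rounds)) {
        roll <- .batch_rollout(net, ctx, flist)
        ex_r <- .build_examples(roll$paths, sp$train, ctx,
                                target_paths = paths)
        net <- .tdnn_sgd(net, ex_r, ctrl, seed = ctrl$seed + 1L + r2)
      }
      model <- structure(list(hmm = fit$params,
                              hmm_trace = fit$loglik_trace,
                              hmm_iter = fit$n_iter,
                              tdnn = net, ctx = ctx,
                              alphabet = data$alphabet, D = data$D,
                              config = list(n_hidden = n_hidden,
                                            context = ctx$name, seed = s)),
                         class = "dtmn")
      ev <- evaluate_model(model, sp$test)
      rows[[length(rows) + 1L]] <-
        data.frame(setting = variants[v], rep = r, seed = s, per = ev$per,
                   hmm_loglik = fit$loglik_trace[length(fit$loglik_trace)])
    }
  }
  .ablation_result(do.call(rbind, rows), "context")
}

.ablation_result <- function(df, variable) {
  agg <- stats::aggregate(per ~ setting, df, function(x)
    c(mean = mean(x), sd = stats::sd(x), median = stats::median(x)))
  summary <- data.frame(setting = agg$setting,
                        mean_per = agg$per[, "mean"],
                        sd_per = agg$per[, "sd"],
                        median_per = agg$per[, "median"])
  structure(df, variable = variable, summary = summary,
            class = c("dtmn_ablation", "data.frame"))
}

#' @export
print.dtmn_ablation <- function(x, ...) {
  cat("DTMN ablation over", attr(x, "variable"), "--",
      nrow(x), "runs\n")
  print(attr(x, "summary"), row.names = FALSE)
  invisible(x)
}
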