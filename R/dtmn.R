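#' Fit a deep time-delay Markov network
#'
#' Two-stage training of the hybrid HMM/TDNN sequence predictor.  Stage 1
#' fits a categorical-emission HMM to the label sequences by Baum-Welch and
#' posterior-decodes a hidden-state target for every time step.  Stage 2
#' trains a time-delay neural network to predict the present hidden state
#' from the window of prior decoded states (binary-encoded; all-zero at
#' pre-sequence boundaries) concatenated with the present feature vector.
#' At prediction time the network runs recursively on its own fed-back
#' states and the emission matrix maps hidden-state posteriors to label
#' posteriors.
#'
#' @param data a fully labeled [sequence_set()].
#' @param n_hidden number of HMM hidden states (default 80).
#' @param context a [tdnn_context()] or preset name (default `"tdnn4"`).
#' @param hidden_dim TDNN hidden width (default 4000).
#' @param control a [tdnn_control()] for the SGD stage.
#' @param hmm_max_iter,hmm_tol Baum-Welch stopping rule.
#' @param refine_rounds number of rollout refinement rounds (default 2).
#'   After the teacher-forced pass, the model is rolled out recursively on
#'   the training sequences and SGD continues on windows built from its own
#'   fed-back states (targets remain the decoded states).  This matches the
#'   training input distribution to the recursive prediction regime, which
#'   otherwise degrades sharply once a fed-back error produces state
#'   patterns never seen under teacher forcing.  0 disables refinement.
#' @param seed optional master seed; when given it seeds both the HMM
#'   initialization and the TDNN stage (overriding `control$seed`).
#' @return An object of class `dtmn`: a list with the fitted `hmm`, `tdnn`,
#'   `ctx`, `alphabet`, feature dimension `D`, the Baum-Welch trace
#'   `hmm_trace`, decoded-path summary, and a `config` snapshot.
#' @seealso [predict.dtmn()], [evaluate_model()], [write_dtmn()]
#' @export
dtmn <- function(data, n_hidden = 80L, context = "tdnn4",
                 hidden_dim = 4000L, control = tdnn_control(),
                 hmm_max_iter = 100L, hmm_tol = 1e-4, refine_rounds = 2L,
                 seed = NULL) {
  stopifnot(inherits(data, "sequence_set"))
  if (length(data$sequences) == 0L)
    stop("no training sequences", call. = FALSE)
  for (s in data$sequences) {
    if (anyNA(s$y))
      stop("sequence '", s$id, "' has an unlabeled step at t = ",
           which(is.na(s$y))[1], "; training needs full labels",
           call. = FALSE)
  }
  if (!inherits(context, "tdnn_context")) context <- tdnn_context(context)
  if (!is.null(seed)) control$seed <- as.integer(seed)
  hmm_seed <- if (is.null(seed)) control$seed else as.integer(seed)

  L <- length(data$alphabet)
  ys <- label_sequences(data)
  hmm0 <- hmm_init(n_hidden, L, seed = hmm_seed)
  fit <- hmm_fit(hmm0, ys, max_iter = hmm_max_iter, tol = hmm_tol)
  paths <- lapply(ys, function(y) hmm_decode(fit$params, y))

  ex <- .build_examples(paths, data, context)
  net <- tdnn_fit(ex, context, n_states = fit$params$N, control = control,
                  hidden_dim = hidden_dim)
  flist <- lapply(data$sequences, `[[`, "f")
  for (r in seq_len(refine_rounds)) {
    roll <- .batch_rollout(net, context, flist)
    ex_r <- .build_examples(roll$paths, data, context, target_paths = paths)
    net <- .tdnn_sgd(net, ex_r, control, seed = control$seed + 1L + r)
  }

  structure(list(hmm = fit$params,
                 hmm_trace = fit$loglik_trace,
                 hmm_iter = fit$n_iter,
                 tdnn = net,
                 ctx = context,
                 alphabet = data$alphabet,
                 D = data$D,
                 config = list(n_hidden = as.integer(n_hidden),
                               context = context$name,
                               hidden_dim = as.integer(hidden_dim),
                               hmm_max_iter = as.integer(hmm_max_iter),
                               hmm_tol = hmm_tol,
                               refine_rounds = as.integer(refine_rounds),
                               seed = hmm_seed,
                               batch_size = control$batch_size,
                               lr = control$lr,
                               momentum = control$momentum,
                               epochs = control$epochs)),
            class = "dtmn")
}

# training tuples (prior-state window, f_t) -> q_t.  Windows come from
# `paths`; targets default to the same paths but can be supplied separately
# (rollout windows with decoded-state targets).
.build_examples <- function(paths, data, ctx, target_paths = paths) {
  W <- ctx$window
  Qs <- list(); Fs <- list(); tg <- list()
  for (i in seq_along(paths)) {
    q <- paths[[i]]
    Tn <- length(q)
    Qw <- matrix(NA_integer_, Tn, W)
    for (k in seq_len(W)) {        # column k holds offset -(W - k + 1)
      off <- -(W - k + 1L)
      src <- seq_len(Tn) + off
      ok <- src >= 1L
      Qw[ok, k] <- q[src[ok]]
    }
    Qs[[i]] <- Qw
    Fs[[i]] <- data$sequences[[i]]$f
    tg[[i]] <- target_paths[[i]]
  }
  list(Q = do.call(rbind, Qs), F = do.call(rbind, Fs),
       target = unlist(tg))
}

# recursive decoding batched across sequences: all sequences advance in
# lockstep, one inference-mode forward per time step
.batch_rollout <- function(net, ctx, flist) {
  W <- ctx$window
  Ts <- vapply(flist, nrow, integer(1))
  paths <- lapply(Ts, function(Tn) integer(Tn))
  posts <- lapply(Ts, function(Tn) matrix(0, Tn, net$N))
  for (t in seq_len(max(Ts))) {
    act <- which(Ts >= t)
    Qwin <- matrix(NA_integer_, length(act), W)
    for (k in seq_len(W)) {
      src <- t - (W - k + 1L)
      if (src >= 1L)
        Qwin[, k] <- vapply(act, function(i) paths[[i]][src], integer(1))
    }
    Fm <- do.call(rbind, lapply(act, function(i)
      flist[[i]][t, , drop = FALSE]))
    prob <- .tdnn_batch_forward(net, Qwin, Fm, mode = "infer")$prob
    qh <- max.col(prob, ties.method = "first")
    for (j in seq_along(act)) {
      posts[[act[j]]][t, ] <- prob[j, ]
      paths[[act[j]]][t] <- qh[j]
    }
  }
  list(paths = paths, posts = posts)
}

#' Predict labels for unlabeled feature sequences
#'
#' Runs the recursive decoding: at each step the TDNN (in inference mode)
#' maps the fed-back window of predicted hidden states plus the present
#' feature vector to a hidden-state posterior; the hard argmax is fed back
#' into the window, while the soft posterior is mapped through the emission
#' matrix to the label posterior
#' `P(y_t = i | f) = sum_j E[j, i] P(q_t = j | f)`.  Ties in either argmax
#' break toward the smaller index.
#'
#' @param object a fitted [dtmn()] model.
#' @param newdata a [sequence_set()] (labels, if present, are ignored) or a
#'   single T x D feature matrix.
#' @param ... unused.
#' @return For a feature matrix, a `dtmn_prediction`: a list with `labels`
#'   (integer), `label_names`, `label_posterior` (T x L), `hidden_path`,
#'   `hidden_posterior` (T x N).  For a sequence set, a named list of
#'   `dtmn_prediction` objects (one per sequence).
#' @export
predict.dtmn <- function(object, newdata, ...) {
  if (inherits(newdata, "sequence_set")) {
    if (newdata$D != object$D)
      stop("feature dimension ", newdata$D, " != model dimension ",
           object$D, call. = FALSE)
    if (length(newdata$sequences) == 0L)
      stop("empty sequence set", call. = FALSE)
    flist <- lapply(newdata$sequences, `[[`, "f")
    roll <- .batch_rollout(object$tdnn, object$ctx, flist)
    out <- lapply(seq_along(flist), function(i)
      .dtmn_label_posterior(object, roll$paths[[i]], roll$posts[[i]]))
    names(out) <- vapply(newdata$sequences, `[[`, character(1), "id")
    return(out)
  }
  if (is.numeric(newdata) && is.null(dim(newdata)))
    newdata <- matrix(newdata, nrow = 1L)
  .dtmn_predict_one(object, newdata)
}

.dtmn_predict_one <- function(model, f) {
  if (!is.matrix(f) || nrow(f) < 1L)
    stop("empty feature sequence", call. = FALSE)
  if (ncol(f) != model$D)
    stop("feature dimension ", ncol(f), " != model dimension ", model$D,
         call. = FALSE)
  roll <- .batch_rollout(model$tdnn, model$ctx, list(f))
  .dtmn_label_posterior(model, roll$paths[[1]], roll$posts[[1]])
}

# map a hidden-state posterior through the emission matrix (label posterior
# P(y_t = i | f) = sum_j E[j, i] P(q_t = j | f)) and take row-wise argmax
.dtmn_label_posterior <- function(model, qhat, hp) {
  lp <- hp %*% model$hmm$E           # T x L label posterior
  rs <- rowSums(lp)
  if (any(abs(rs - 1) > 1e-6))
    stop("label posterior rows do not sum to 1 (max dev ",
         format(max(abs(rs - 1))), "); emission matrix not stochastic?",
         call. = FALSE)
  lp <- lp / rs
  yhat <- apply(lp, 1L, which.max)
  structure(list(labels = as.integer(yhat),
                 label_names = as.character(model$alphabet)[yhat],
                 label_posterior = lp,
                 hidden_path = qhat,
                 hidden_posterior = hp),
            class = "dtmn_prediction")
}

#' @export
print.dtmn_prediction <- function(x, ...) {
  Tn <- length(x$labels)
  cat("DTMN prediction: T =", Tn, "steps\n")
  show <- utils::head(x$label_names, 10L)
  cat("Labels: ", paste(show, collapse = ", "),
      if (Tn > 10L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Evaluate a DTMN model on labeled data
#'
#' Predicts every sequence and reports the prediction error rate: the
#' percentage of time steps whose predicted label differs from the true one,
#' pooled over all sequences, plus a per-sequence breakdown and the L x L
#' confusion matrix (rows = true label).
#'
#' @param model a fitted [dtmn()] model.
#' @param data a fully labeled [sequence_set()].
#' @return An object of class `dtmn_eval`: list with `per` (percent),
#'   `per_sequence` (named numeric), `confusion`, `n_steps`.
#' @export
evaluate_model <- function(model, data) {
  stopifnot(inherits(model, "dtmn"), inherits(data, "sequence_set"))
  if (data$D != model$D)
    stop("feature dimension ", data$D, " != model dimension ", model$D,
         call. = FALSE)
  preds <- predict(model, data)
  L <- length(model$alphabet)
  conf <- matrix(0L, L, L,
                 dimnames = list(true = as.character(model$alphabet),
                                 pred = as.character(model$alphabet)))
  per_seq <- numeric(length(preds))
  for (i in seq_along(preds)) {
    y <- data$sequences[[i]]$y
    if (anyNA(y))
      stop("sequence '", data$sequences[[i]]$id,
           "' has unlabeled steps; evaluation needs full labels",
           call. = FALSE)
    yh <- preds[[i]]$labels
    per_seq[i] <- per(y, yh)
    for (t in seq_along(y)) conf[y[t], yh[t]] <- conf[y[t], yh[t]] + 1L
  }
  names(per_seq) <- names(preds)
  total <- sum(conf)
  structure(list(per = 100 * (total - sum(diag(conf))) / total,
                 per_sequence = per_seq,
                 confusion = conf,
                 n_steps = total,
                 config = model$config),
            class = "dtmn_eval")
}

#' @export
print.dtmn_eval <- function(x, ...) {
  cat(sprintf("Prediction error rate: %.2f%% over %d steps (%d sequences)\n",
              x$per, x$n_steps, length(x$per_sequence)))
  cat("Confusion matrix (rows = true):\n")
  print(x$confusion)
  invisible(x)
}

#' @export
print.dtmn <- function(x, ...) {
  cat("Deep time-delay Markov network\n")
  cat("  Alphabet:   ", paste(as.character(x$alphabet), collapse = ", "),
      "\n", sep = "")
  cat("  HMM:        N = ", x$hmm$N, " hidden states, ",
      x$hmm_iter, " Baum-Welch iterations (loglik ",
      format(x$hmm_trace[length(x$hmm_trace)], digits = 6), ")\n", sep = "")
  cat("  TDNN:       context '", x$ctx$name, "', hidden width ",
      x$tdnn$h4, ", final loss ",
      format(x$tdnn$loss_trace[length(x$tdnn$loss_trace)], digits = 4),
      "\n", sep = "")
  cat("  Features:   D = ", x$D, "\n", sep = "")
  invisible(x)
}

#' @export
summary.dtmn <- function(object, ...) {
  out <- list(config = object$config,
              hmm_trace = object$hmm_trace,
              tdnn_loss = object$tdnn$loss_trace)
  class(out) <- "summary.dtmn"
  out
}

#' @export
print.summary.dtmn <- function(x, ...) {
  cat("DTMN fit summary\n")
  cat("Config:\n")
  for (k in names(x$config))
    cat("  ", k, ": ", format(x$config[[k]]), "\n", sep = "")
  cat("Baum-Welch log-likelihood trace (", length(x$hmm_trace),
      " iterations):\n  ", sep = "")
  cat(format(utils::head(x$hmm_trace, 3), digits = 6), "...",
      format(utils::tail(x$hmm_trace, 1), digits = 6), "\n")
  cat("TDNN epoch loss: first ",
      format(x$tdnn_loss[1], digits = 4), ", last ",
      format(x$tdnn_loss[length(x$tdnn_loss)], digits = 4), "\n", sep = "")
  invisible(x)
}

#' Per-sequence holdout split
#'
#' Randomly assigns whole sequences to a held-out evaluation set.
#'
#' @param data a [sequence_set()].
#' @param fraction fraction of sequences held out (default 0.2).
#' @param seed RNG seed.
#' @return List with `train` and `test` sequence sets.
#' @export
split_holdout <- function(data, fraction = 0.2, seed = 1L) {
  stopifnot(inherits(data, "sequence_set"))
  n <- length(data$sequences)
  if (n < 2L) stop("need at least 2 sequences to split", call. = FALSE)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  n_test <- max(1L, round(fraction * n))
  test_idx <- sort(sample.int(n, n_test))
  list(train = sequence_set(data$sequences[-test_idx], data$alphabet),
       test = sequence_set(data$sequences[test_idx], data$alphabet))
}
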