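#' Temporal context specifications for the TDNN
#'
#' A context specification fixes which prior hidden states each network layer
#' consumes, as absolute negative time offsets relative to the present step.
#' Six named presets (`tdnn1` .. `tdnn6`) encode the published variants of
#' the layer-wise context sweep; `table2` is the default splicing structure
#' with Layer-1 holding the full window `{-5..-1}` and Layer-2 the
#' sub-sampled pair `{-3,-1}`.  Layer-3 always splices the offset `-1` output
#' with the present feature transform.
#'
#' @param name preset name (`"tdnn1"` .. `"tdnn6"`, `"table2"`) or
#'   `"custom"`, in which case `network`, `l1`, `l2` must be given.
#' @param network set of strictly negative offsets covered by the input
#'   window (custom contexts only).
#' @param l1,l2 offset sets consumed by Layer-1 and Layer-2.
#' @return An object of class `tdnn_context` with elements `name`, `network`,
#'   `l1`, `l2`, `l3` (always `-1`), `window` (window length).
#' @export
#' @examples
#' tdnn_context("tdnn4")
tdnn_context <- function(name = "tdnn4", network = NULL, l1 = NULL,
                         l2 = NULL) {
  presets <- list(
    tdnn1  = list(network = -1L,        l1 = -1L,            l2 = -1L),
    tdnn2  = list(network = c(-2L,-1L), l1 = c(-2L,-1L),     l2 = -1L),
    tdnn3  = list(network = -3:-1,      l1 = c(-2L,-1L),     l2 = c(-2L,-1L)),
    tdnn4  = list(network = -5:-1,      l1 = -3:-1,          l2 = c(-3L,-1L)),
    tdnn5  = list(network = -7:-1,      l1 = -3:-1,          l2 = c(-5L,-3L,-1L)),
    tdnn6  = list(network = -9:-1,      l1 = -5:-1,          l2 = c(-9L,-5L,-1L)),
    table2 = list(network = -5:-1,      l1 = -5:-1,          l2 = c(-3L,-1L)))
  if (name != "custom") {
    if (!name %in% names(presets))
      stop("unknown context preset '", name, "'; known: ",
           paste(c(names(presets), "custom"), collapse = ", "),
           call. = FALSE)
    p <- presets[[name]]
    network <- p$network; l1 <- p$l1; l2 <- p$l2
  } else {
    if (is.null(network) || is.null(l1) || is.null(l2))
      stop("custom context needs network, l1 and l2 offset sets",
           call. = FALSE)
  }
  network <- sort(unique(as.integer(network)))
  l1 <- sort(unique(as.integer(l1)))
  l2 <- sort(unique(as.integer(l2)))
  if (any(network >= 0L) || any(l1 >= 0L) || any(l2 >= 0L))
    stop("context offsets must be strictly negative", call. = FALSE)
  if (!all(l1 %in% network) || !all(l2 %in% network))
    stop("layer offsets must lie inside the network context", call. = FALSE)
  structure(list(name = name, network = network, l1 = l1, l2 = l2,
                 l3 = -1L, window = -min(network)),
            class = "tdnn_context")
}

#' @export
print.tdnn_context <- function(x, ...) {
  fmt <- function(v) paste0("{", paste(v, collapse = ","), "}")
  cat("TDNN context '", x$name, "': network ", fmt(x$network),
      ", layer-1 ", fmt(x$l1), ", layer-2 ", fmt(x$l2),
      ", layer-3 {", x$l3, ", f_t}\n", sep = "")
  invisible(x)
}

#' Binary (one-hot) encoding of a hidden state
#'
#' Encodes hidden state `q` as a length-N indicator vector with a single 1 at
#' position `q`.  The absent marker `NA` (a pre-sequence boundary, where no
#' prior state exists) encodes as the all-zero vector.
#'
#' @param q hidden state index in `1..N`, or `NA`.
#' @param N number of hidden states.
#' @return Numeric length-N vector.
#' @export
alpha_encode <- function(q, N) {
  N <- as.integer(N)
  v <- numeric(N)
  if (length(q) != 1L) stop("q must be a single state", call. = FALSE)
  if (is.na(q)) return(v)
  q <- as.integer(q)
  if (q < 1L || q > N)
    stop("state ", q, " outside 1..", N, call. = FALSE)
  v[q] <- 1
  v
}

# batch version: integer vector (NA allowed) -> n x N indicator matrix
.alpha_mat <- function(q, N) {
  m <- matrix(0, length(q), N)
  ok <- which(!is.na(q))
  if (length(ok)) m[cbind(ok, q[ok])] <- 1
  m
}

#' Numerically stable softmax
#'
#' `softmax(z)_c = exp(z_c) / sum_d exp(z_d)`, computed after subtracting the
#' maximum entry so large logits do not overflow.
#'
#' @param z numeric vector of finite logits.
#' @return Probability vector summing to 1.
#' @export
softmax <- function(z) {
  if (any(!is.finite(z))) stop("non-finite logits", call. = FALSE)
  e <- exp(z - max(z))
  e / sum(e)
}

# row-wise softmax for a batch matrix
.softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# ---- batch normalization --------------------------------------------------

.BN_EPS <- 1e-5

.bn_new <- function(width) list(rmean = numeric(width), rvar = rep(1, width))

# a: n x w pre-activation; gamma/delta learned scale/shift.
# train mode uses batch moments and updates running stats in 'stats'.
.bn_forward <- function(a, gamma, delta, stats, mode, momentum = 0.9) {
  if (mode == "train") {
    n <- nrow(a)
    mu <- colMeans(a)
    va <- colMeans(a^2) - mu^2
    va[va < 0] <- 0
    ivar <- 1 / sqrt(va + .BN_EPS)
    xhat <- sweep(sweep(a, 2L, mu), 2L, ivar, `*`)
    stats$rmean <- momentum * stats$rmean + (1 - momentum) * mu
    stats$rvar <- momentum * stats$rvar + (1 - momentum) * va
    out <- sweep(sweep(xhat, 2L, gamma, `*`), 2L, delta, `+`)
    list(out = out, stats = stats,
         cache = list(xhat = xhat, ivar = ivar, gamma = gamma))
  } else {
    ivar <- 1 / sqrt(stats$rvar + .BN_EPS)
    xhat <- sweep(sweep(a, 2L, stats$rmean), 2L, ivar, `*`)
    out <- sweep(sweep(xhat, 2L, gamma, `*`), 2L, delta, `+`)
    list(out = out, stats = stats, cache = NULL)
  }
}

# dy: gradient wrt BN output. Returns da and parameter gradients.
.bn_backward <- function(dy, cache) {
  xhat <- cache$xhat; ivar <- cache$ivar; gamma <- cache$gamma
  n <- nrow(dy)
  dgamma <- colSums(dy * xhat)
  ddelta <- colSums(dy)
  dxhat <- sweep(dy, 2L, gamma, `*`)
  da <- sweep(dxhat - matrix(colMeans(dxhat), n, ncol(dy), byrow = TRUE) -
                xhat * matrix(colMeans(dxhat * xhat), n, ncol(dy),
                              byrow = TRUE),
              2L, ivar, `*`)
  list(da = da, dgamma = dgamma, ddelta = ddelta)
}

# ---- parameter container --------------------------------------------------

.k1 <- function(stem, o) sprintf("%s@%d", stem, o)

# He-style initialization for one weight matrix
.winit <- function(nin, nout, scale = 1) {
  matrix(stats::rnorm(nin * nout, sd = scale * sqrt(2 / max(nin, 1))),
         nin, nout)
}

#' @keywords internal
.tdnn_init <- function(ctx, n_states, D, hidden_dim = 4000L,
                       beta_dim = NULL, seed = 1L) {
  if (is.null(beta_dim)) beta_dim <- D
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  N <- as.integer(n_states)
  h1 <- h2 <- h4 <- as.integer(hidden_dim)
  theta <- list()
  bn <- list()
  for (o in ctx$l1) {
    theta[[.k1("W1", o)]] <- .winit(N, h1)
    theta[[.k1("b1", o)]] <- numeric(h1)
    theta[[.k1("g1", o)]] <- rep(1, h1)
    theta[[.k1("d1", o)]] <- numeric(h1)
    bn[[.k1("bn1", o)]] <- .bn_new(h1)
  }
  in2 <- sum(ifelse(ctx$l2 %in% ctx$l1, h1, N))
  theta$W2 <- .winit(in2, h2); theta$b2 <- numeric(h2)
  theta$g2 <- rep(1, h2); theta$d2 <- numeric(h2)
  bn$bn2 <- .bn_new(h2)
  # beta: learned affine feature transform, near-identity at init
  Wb <- matrix(0, D, beta_dim)
  k <- seq_len(min(D, beta_dim))
  Wb[cbind(k, k)] <- 1
  Wb <- Wb + matrix(stats::rnorm(D * beta_dim, sd = 0.01), D, beta_dim)
  theta$Wb <- Wb; theta$bb <- numeric(beta_dim)
  theta$W4 <- .winit(h2 + beta_dim, h4); theta$b4 <- numeric(h4)
  theta$g4 <- rep(1, h4); theta$d4 <- numeric(h4)
  bn$bn4 <- .bn_new(h4)
  theta$W5 <- .winit(h4, N, scale = 0.5); theta$b5 <- numeric(N)
  structure(list(ctx = ctx, N = N, D = as.integer(D),
                 h1 = h1, h2 = h2, h4 = h4,
                 beta_dim = as.integer(beta_dim),
                 theta = theta, bn = bn, loss_trace = numeric(0)),
            class = "tdnn")
}

#' @export
print.tdnn <- function(x, ...) {
  cat("TDNN: ", x$N, " classes, D = ", x$D, ", hidden width ", x$h4,
      ", context '", x$ctx$name, "'\n", sep = "")
  if (length(x$loss_trace))
    cat("Final training loss: ",
        format(x$loss_trace[length(x$loss_trace)], digits = 5), "\n",
        sep = "")
  invisible(x)
}

# column of the window matrix corresponding to offset o (columns run from
# offset -window .. -1 left to right)
.win_col <- function(ctx, o) ctx$window + o + 1L

# full forward pass over a batch.
# Qwin: n x window integer matrix (NA = absent), F: n x D.
.tdnn_batch_forward <- function(net, Qwin, Fmat, mode = c("infer", "train"),
                                bn_momentum = 0.9) {
  mode <- match.arg(mode)
  ctx <- net$ctx
  if (ncol(Qwin) != ctx$window)
    stop("state window has ", ncol(Qwin), " columns, context needs ",
         ctx$window, call. = FALSE)
  if (ncol(Fmat) != net$D)
    stop("feature dimension ", ncol(Fmat), " != model dimension ", net$D,
         call. = FALSE)
  th <- net$theta
  cache <- list(alpha = list(), h1 = list(), bn1 = list(), relu1 = list())
  # layer 1: time-distributed affine+BN+ReLU per offset, untied weights
  for (o in ctx$l1) {
    X <- .alpha_mat(Qwin[, .win_col(ctx, o)], net$N)
    a <- sweep(X %*% th[[.k1("W1", o)]], 2L, th[[.k1("b1", o)]], `+`)
    bnres <- .bn_forward(a, th[[.k1("g1", o)]], th[[.k1("d1", o)]],
                         net$bn[[.k1("bn1", o)]], mode, bn_momentum)
    if (mode == "train") net$bn[[.k1("bn1", o)]] <- bnres$stats
    h <- pmax(bnres$out, 0)
    ko <- as.character(o)
    cache$alpha[[ko]] <- X
    cache$bn1[[ko]] <- bnres$cache
    cache$relu1[[ko]] <- bnres$out > 0
    cache$h1[[ko]] <- h
  }
  # layer 2: splice the sub-sampled offsets; offsets outside layer-1's
  # coverage are spliced directly from the state encoding
  parts <- lapply(ctx$l2, function(o) {
    if (o %in% ctx$l1) cache$h1[[as.character(o)]]
    else .alpha_mat(Qwin[, .win_col(ctx, o)], net$N)
  })
  X2 <- do.call(cbind, parts)
  a2 <- sweep(X2 %*% th$W2, 2L, th$b2, `+`)
  bn2 <- .bn_forward(a2, th$g2, th$d2, net$bn$bn2, mode, bn_momentum)
  if (mode == "train") net$bn$bn2 <- bn2$stats
  H2 <- pmax(bn2$out, 0)
  # layer 3: concatenate with the feature transform beta(f_t)
  Fb <- sweep(Fmat %*% th$Wb, 2L, th$bb, `+`)
  X3 <- cbind(H2, Fb)
  # layer 4: fully connected
  a4 <- sweep(X3 %*% th$W4, 2L, th$b4, `+`)
  bn4 <- .bn_forward(a4, th$g4, th$d4, net$bn$bn4, mode, bn_momentum)
  if (mode == "train") net$bn$bn4 <- bn4$stats
  H4 <- pmax(bn4$out, 0)
  # layer 5: affine + softmax
  logits <- sweep(H4 %*% th$W5, 2L, th$b5, `+`)
  prob <- .softmax_rows(logits)
  list(prob = prob, net = net,
       cache = if (mode == "train")
         c(cache, list(X2 = X2, bn2 = bn2$cache, relu2 = bn2$out > 0,
                       H2 = H2, Fmat = Fmat, X3 = X3, bn4 = bn4$cache,
                       relu4 = bn4$out > 0, H4 = H4, prob = prob))
       else NULL)
}

# gradient of mean cross-entropy wrt all learned parameters
.tdnn_backward <- function(net, cache, target) {
  ctx <- net$ctx; th <- net$theta
  n <- nrow(cache$prob)
  g <- list()
  dlog <- cache$prob
  dlog[cbind(seq_len(n), target)] <- dlog[cbind(seq_len(n), target)] - 1
  dlog <- dlog / n
  g$W5 <- crossprod(cache$H4, dlog)
  g$b5 <- colSums(dlog)
  dH4 <- tcrossprod(dlog, th$W5) * cache$relu4
  bb4 <- .bn_backward(dH4, cache$bn4)
  g$g4 <- bb4$dgamma; g$d4 <- bb4$ddelta
  g$W4 <- crossprod(cache$X3, bb4$da)
  g$b4 <- colSums(bb4$da)
  dX3 <- tcrossprod(bb4$da, th$W4)
  dH2 <- dX3[, seq_len(net$h2), drop = FALSE]
  dFb <- dX3[, net$h2 + seq_len(net$beta_dim), drop = FALSE]
  g$Wb <- crossprod(cache$Fmat, dFb)
  g$bb <- colSums(dFb)
  dH2 <- dH2 * cache$relu2
  bb2 <- .bn_backward(dH2, cache$bn2)
  g$g2 <- bb2$dgamma; g$d2 <- bb2$ddelta
  g$W2 <- crossprod(cache$X2, bb2$da)
  g$b2 <- colSums(bb2$da)
  dX2 <- tcrossprod(bb2$da, th$W2)
  col0 <- 0L
  for (o in ctx$l2) {
    w <- if (o %in% ctx$l1) net$h1 else net$N
    dpart <- dX2[, col0 + seq_len(w), drop = FALSE]
    col0 <- col0 + w
    if (!o %in% ctx$l1) next  # raw encoding splice: no parameters below
    ko <- as.character(o)
    dh <- dpart * cache$relu1[[ko]]
    bb1 <- .bn_backward(dh, cache$bn1[[ko]])
    g[[.k1("g1", o)]] <- bb1$dgamma
    g[[.k1("d1", o)]] <- bb1$ddelta
    g[[.k1("W1", o)]] <- crossprod(cache$alpha[[ko]], bb1$da)
    g[[.k1("b1", o)]] <- colSums(bb1$da)
  }
  # layer-1 offsets never consumed by layer 2 get zero gradient
  for (o in setdiff(ctx$l1, ctx$l2)) {
    g[[.k1("g1", o)]] <- 0 * th[[.k1("g1", o)]]
    g[[.k1("d1", o)]] <- 0 * th[[.k1("d1", o)]]
    g[[.k1("W1", o)]] <- 0 * th[[.k1("W1", o)]]
    g[[.k1("b1", o)]] <- 0 * th[[.k1("b1", o)]]
  }
  g
}

#' TDNN forward pass for a single time step
#'
#' Maps the window of prior hidden states plus the present feature vector to
#' a probability distribution over present hidden states.  In `infer` mode
#' batch normalization uses the frozen running moments, so the output is a
#' pure function of the parameters and inputs.
#'
#' @param net a fitted `tdnn` (from [tdnn_fit()]).
#' @param q_window integer vector of prior hidden states, ordered oldest
#'   first, length equal to the context window; `NA` marks absent
#'   (pre-sequence) positions.
#' @param f numeric feature vector of length D.
#' @param mode `"infer"` (default) or `"train"`.
#' @return Probability vector over the `net$N` hidden states.
#' @export
tdnn_forward <- function(net, q_window, f, mode = "infer") {
  stopifnot(inherits(net, "tdnn"))
  Qwin <- matrix(as.integer(q_window), 1L)
  Fmat <- matrix(as.numeric(f), 1L)
  .tdnn_batch_forward(net, Qwin, Fmat, mode = mode)$prob[1L, ]
}

#' Training configuration for SGD
#'
#' @param batch_size mini-batch size (default 256).
#' @param lr learning rate (> 0; default 0.01).
#' @param momentum classical momentum coefficient (default 0.9).
#' @param epochs passes over the training set (default 30).
#' @param bn_momentum running-moment momentum for batch normalization.
#' @param seed RNG seed controlling initialization and shuffling.
#' @return A list of class `tdnn_control`.
#' @export
tdnn_control <- function(batch_size = 256L, lr = 0.01, momentum = 0.9,
                         epochs = 30L, bn_momentum = 0.9, seed = 1L) {
  if (batch_size < 1L) stop("batch_size must be >= 1", call. = FALSE)
  if (lr < 0) stop("learning rate must be >= 0", call. = FALSE)
  structure(list(batch_size = as.integer(batch_size), lr = lr,
                 momentum = momentum, epochs = as.integer(epochs),
                 bn_momentum = bn_momentum, seed = as.integer(seed)),
            class = "tdnn_control")
}

#' Train a TDNN by mini-batch SGD
#'
#' Minimizes the mean negative log-probability of the target hidden state
#' (cross-entropy after the softmax layer) with classical momentum, shuffling
#' the examples every epoch.  A fixed seed gives an identical parameter
#' trajectory.
#'
#' @param examples list with `Q` (n x window integer matrix of prior-state
#'   windows, `NA` for absent), `F` (n x D feature matrix), `target`
#'   (length-n integer vector of present hidden states in `1..n_states`).
#' @param ctx a [tdnn_context()].
#' @param n_states number of hidden-state classes.
#' @param control a [tdnn_control()].
#' @param hidden_dim hidden width of layers 1, 2 and 4 (default 4000).
#' @param beta_dim width of the feature transform (default: D).
#' @return A fitted object of class `tdnn` with frozen batch-norm running
#'   moments and the per-epoch mean loss in `$loss_trace`.
#' @export
tdnn_fit <- function(examples, ctx, n_states, control = tdnn_control(),
                     hidden_dim = 4000L, beta_dim = NULL) {
  stopifnot(inherits(ctx, "tdnn_context"))
  n <- length(examples$target)
  if (n < 1L) stop("no training examples", call. = FALSE)
  if (nrow(examples$Q) != n || nrow(examples$F) != n)
    stop("examples Q, F and target disagree in length", call. = FALSE)
  if (any(is.na(examples$target)) || any(examples$target < 1L) ||
      any(examples$target > n_states))
    stop("targets must lie in 1..", n_states, call. = FALSE)
  net <- .tdnn_init(ctx, n_states, ncol(examples$F), hidden_dim, beta_dim,
                    seed = control$seed)
  net <- .tdnn_sgd(net, examples, control, seed = control$seed + 1L)
  net$control <- control
  net
}

# SGD epochs over a fixed example set; appends to the loss trace so a
# warm-started continuation (e.g. a rollout refinement round) keeps history
.tdnn_sgd <- function(net, examples, control, seed,
                      epochs = control$epochs) {
  n <- length(examples$target)
  vel <- lapply(net$theta, function(p) 0 * p)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  trace <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    starts <- seq(1L, n, by = control$batch_size)
    losses <- numeric(length(starts))
    for (bi in seq_along(starts)) {
      idx <- ord[starts[bi]:min(starts[bi] + control$batch_size - 1L, n)]
      fw <- .tdnn_batch_forward(net, examples$Q[idx, , drop = FALSE],
                                examples$F[idx, , drop = FALSE],
                                mode = "train",
                                bn_momentum = control$bn_momentum)
      net <- fw$net
      p_t <- fw$prob[cbind(seq_along(idx), examples$target[idx])]
      losses[bi] <- -mean(log(pmax(p_t, 1e-300)))
      if (control$lr > 0) {
        grad <- .tdnn_backward(net, fw$cache, examples$target[idx])
        for (k in names(grad)) {
          vel[[k]] <- control$momentum * vel[[k]] - control$lr * grad[[k]]
          net$theta[[k]] <- net$theta[[k]] + vel[[k]]
        }
      }
    }
    trace[ep] <- mean(losses)
  }
  net$loss_trace <- c(net$loss_trace, trace)
  net
}

# ---- serialization helpers ------------------------------------------------

.tdnn_pack <- function(net) {
  list(ctx_name = net$ctx$name, N = net$N, D = net$D, h1 = net$h1,
       h2 = net$h2, h4 = net$h4, beta_dim = net$beta_dim,
       theta = net$theta,
       bn = net$bn,
       loss_trace = net$loss_trace)
}

.tdnn_unpack <- function(obj) {
  ctx <- tdnn_context(obj$ctx_name)
  theta <- obj$theta
  # JSON round-trips matrices as nested arrays or flattens length-1 dims
  shape2 <- function(x) if (is.matrix(x)) x else .as_matrix(x)
  for (i in seq_along(theta)) {
    if (grepl("^W", names(theta)[i])) theta[[i]] <- shape2(theta[[i]])
    else theta[[i]] <- as.numeric(theta[[i]])
  }
  bn <- lapply(obj$bn, function(s)
    list(rmean = as.numeric(s$rmean), rvar = as.numeric(s$rvar)))
  structure(list(ctx = ctx, N = as.integer(obj$N), D = as.integer(obj$D),
                 h1 = as.integer(obj$h1), h2 = as.integer(obj$h2),
                 h4 = as.integer(obj$h4),
                 beta_dim = as.integer(obj$beta_dim),
                 theta = theta, bn = bn,
                 loss_trace = as.numeric(obj$loss_trace)),
            class = "tdnn")
}
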