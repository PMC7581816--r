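#' Random initialization of a categorical-emission HMM
#'
#' Draws every entry of the initial distribution, transition matrix and
#' emission matrix uniformly on (0, 1) and normalizes each row to sum to 1.
#' The same seed always yields the same parameters.
#'
#' @param N number of hidden states (>= 1).  The package default elsewhere is
#'   80 hidden states over the 5-label alphabet.
#' @param L number of emission labels (>= 2).
#' @param seed integer RNG seed.
#' @return An object of class `cat_hmm`: a list with `N`, `L`, `pi`
#'   (length-N), `A` (N x N, rows = source state), `E` (N x L, row j is the
#'   label distribution of hidden state j).
#' @export
hmm_init <- function(N, L, seed = 1L) {
  N <- as.integer(N); L <- as.integer(L)
  if (is.na(N) || N < 1L) stop("N must be >= 1", call. = FALSE)
  if (is.na(L) || L < 2L) stop("L must be >= 2", call. = FALSE)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  norm_rows <- function(m) m / rowSums(m)
  pi0 <- stats::runif(N); pi0 <- pi0 / sum(pi0)
  A <- norm_rows(matrix(stats::runif(N * N), N, N))
  E <- norm_rows(matrix(stats::runif(N * L), N, L))
  structure(list(N = N, L = L, pi = pi0, A = A, E = E), class = "cat_hmm")
}

#' @export
print.cat_hmm <- function(x, ...) {
  cat("Categorical-emission HMM: N =", x$N, "hidden states, L =", x$L,
      "labels\n")
  invisible(x)
}

.check_hmm_labels <- function(y, L) {
  y <- as.integer(y)
  if (length(y) < 1L) stop("empty label sequence", call. = FALSE)
  if (anyNA(y) || any(y < 1L) || any(y > L))
    stop("label sequence contains indices outside 1..", L, call. = FALSE)
  y
}

#' Forward-backward posteriors for a label sequence
#'
#' Computes the per-step hidden-state posterior gamma and the sequence
#' log-likelihood with per-step scaling, so sequences of length 1000+ do not
#' underflow.
#'
#' @param params a `cat_hmm` (see [hmm_init()]).
#' @param y integer label sequence (values in `1..L`).
#' @return List with `gamma` (T x N matrix, rows sum to 1), `loglik`, and
#'   `xi_sum` (N x N expected transition counts, used by [hmm_fit()]).
#' @export
hmm_forward_backward <- function(params, y) {
  y <- .check_hmm_labels(y, params$L)
  .fb_cpp(params$pi, params$A, params$E, y - 1L)
}

# renormalize rows; rows with (near-)zero mass fall back to uniform
.fix_rows <- function(m, floor = 1e-12) {
  rs <- rowSums(m)
  bad <- !is.finite(rs) | rs < floor
  if (any(bad)) m[bad, ] <- 1 / ncol(m)
  m / rowSums(m)
}

#' Fit an HMM to label sequences by Baum-Welch
#'
#' Expectation-maximization for the categorical-emission HMM: the E-step runs
#' scaled forward-backward over every sequence, the M-step re-estimates pi, A
#' and E from the accumulated posteriors.  Iterates until the total
#' log-likelihood improves by less than `tol` or `max_iter` is reached.
#'
#' @param params0 initial `cat_hmm` parameters (e.g. from [hmm_init()]).
#' @param ys list of integer label sequences (or a single vector).
#' @param max_iter maximum EM iterations (default 100).
#' @param tol absolute tolerance on total log-likelihood change (default 1e-4).
#' @return List with `params` (fitted `cat_hmm`), `loglik_trace`
#'   (log-likelihood of the parameters entering each iteration;
#'   non-decreasing up to numerical slack), and `n_iter`.
#' @export
hmm_fit <- function(params0, ys, max_iter = 100L, tol = 1e-4) {
  if (!is.list(ys)) ys <- list(ys)
  if (length(ys) == 0L) stop("no training sequences", call. = FALSE)
  if (max_iter < 1L) stop("max_iter must be >= 1", call. = FALSE)
  ys <- lapply(ys, .check_hmm_labels, L = params0$L)
  params <- params0
  N <- params$N; L <- params$L
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    ll <- 0
    pi_acc <- numeric(N)
    xi_acc <- matrix(0, N, N)
    e_acc <- matrix(0, N, L)
    for (y in ys) {
      fb <- hmm_forward_backward(params, y)
      ll <- ll + fb$loglik
      pi_acc <- pi_acc + fb$gamma[1, ]
      xi_acc <- xi_acc + fb$xi_sum
      for (l in seq_len(L)) {
        idx <- which(y == l)
        if (length(idx))
          e_acc[, l] <- e_acc[, l] + colSums(fb$gamma[idx, , drop = FALSE])
      }
    }
    trace <- c(trace, ll)
    if (it > 1L && abs(trace[it] - trace[it - 1L]) < tol) break
    s <- sum(pi_acc)
    params$pi <- if (s > 1e-12) pi_acc / s else rep(1 / N, N)
    params$A <- .fix_rows(xi_acc)
    params$E <- .fix_rows(e_acc)
    if (it == max_iter) break
  }
  list(params = params, loglik_trace = trace, n_iter = length(trace))
}

#' Baum-Welch with random restarts
#'
#' EM converges to a local optimum of the likelihood, and categorical HMMs
#' have many.  This convenience wrapper runs [hmm_fit()] from `restarts`
#' independent random initializations (seeds `seed, seed + 1, ...`) and
#' returns the run with the highest final log-likelihood — selection is by
#' likelihood only.
#'
#' @param ys list of integer label sequences.
#' @param N,L state and label counts.
#' @param restarts number of random initializations (default 5).
#' @param seed base seed.
#' @param max_iter,tol forwarded to [hmm_fit()].
#' @return As [hmm_fit()], with an extra `init_seed` element naming the
#'   winning initialization.
#' @export
hmm_fit_restarts <- function(ys, N, L, restarts = 5L, seed = 0L,
                             max_iter = 100L, tol = 1e-4) {
  best <- NULL
  for (r in seq_len(restarts)) {
    s <- seed + r - 1L
    fit <- hmm_fit(hmm_init(N, L, seed = s), ys, max_iter = max_iter,
                   tol = tol)
    ll <- fit$loglik_trace[fit$n_iter]
    if (is.null(best) || ll > best$loglik_trace[best$n_iter]) {
      best <- fit
      best$init_seed <- s
    }
  }
  best
}

#' Posterior decoding of hidden states
#'
#' Assigns each time step the hidden state maximizing its marginal posterior
#' gamma (not the jointly most likely Viterbi path).  Exact ties go to the
#' smallest state index.
#'
#' @param params a `cat_hmm`.
#' @param y integer label sequence.
#' @return Integer vector `q` of hidden states, length `length(y)`.
#' @export
hmm_decode <- function(params, y) {
  fb <- hmm_forward_backward(params, y)
  apply(fb$gamma, 1L, which.max)
}

#' Simulate label sequences from an HMM
#'
#' @param params a `cat_hmm`.
#' @param lengths integer vector of sequence lengths.
#' @param seed integer RNG seed.
#' @return List of integer label sequences.
#' @export
hmm_simulate <- function(params, lengths, seed = 1L) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  lapply(lengths, function(Tn) {
    q <- integer(Tn); y <- integer(Tn)
    q[1] <- sample.int(params$N, 1L, prob = params$pi)
    y[1] <- sample.int(params$L, 1L, prob = params$E[q[1], ])
    if (Tn > 1L) for (t in 2:Tn) {
      q[t] <- sample.int(params$N, 1L, prob = params$A[q[t - 1L], ])
      y[t] <- sample.int(params$L, 1L, prob = params$E[q[t], ])
    }
    y
  })
}

# RNG bookkeeping: seeded helpers must not clobber the caller's RNG stream
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
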