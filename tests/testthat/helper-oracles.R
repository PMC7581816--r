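# Brute-force HMM posteriors: enumerate all N^T hidden paths.  Independent
# of the recursive forward-backward implementation; only feasible for tiny
# N and T, which is the point.
bf_forward_backward <- function(params, y) {
  N <- params$N
  Tn <- length(y)
  paths <- as.matrix(expand.grid(rep(list(seq_len(N)), Tn)))
  probs <- apply(paths, 1L, function(q) {
    p <- params$pi[q[1]] * params$E[q[1], y[1]]
    if (Tn > 1L) for (t in 2:Tn)
      p <- p * params$A[q[t - 1L], q[t]] * params$E[q[t], y[t]]
    p
  })
  tot <- sum(probs)
  gamma <- matrix(0, Tn, N)
  for (t in seq_len(Tn)) for (j in seq_len(N))
    gamma[t, j] <- sum(probs[paths[, t] == j]) / tot
  list(gamma = gamma, loglik = log(tot))
}

# random HMM instance + label sequence for property sweeps
random_hmm_instance <- function(N, L, Tn) {
  norm_rows <- function(m) m / rowSums(m)
  params <- structure(list(
    N = N, L = L,
    pi = {p <- runif(N); p / sum(p)},
    A = norm_rows(matrix(runif(N * N), N, N)),
    E = norm_rows(matrix(runif(N * L), N, L))), class = "cat_hmm")
  list(params = params, y = sample.int(L, Tn, replace = TRUE))
}

# greedy matching of fitted hidden states to true states by emission rows,
# then per-row total-variation distance of the permuted transition matrix
match_and_tv <- function(true_hmm, fit_hmm) {
  N <- true_hmm$N
  perm <- integer(N)
  avail <- seq_len(N)
  for (i in seq_len(N)) {
    d <- vapply(avail, function(j)
      sum(abs(true_hmm$E[i, ] - fit_hmm$E[j, ])), numeric(1))
    perm[i] <- avail[which.min(d)]
    avail <- setdiff(avail, perm[i])
  }
  A_hat <- fit_hmm$A[perm, perm, drop = FALSE]
  apply(abs(A_hat - true_hmm$A), 1L, sum) / 2
}

# per-row total variation between two row-stochastic matrices
row_tv <- function(P, Q) apply(abs(P - Q), 1L, sum) / 2

# small labeled sequence set built in code
tiny_set <- function(n_seq = 3, len = 12, D = 3, seed = 1) {
  g <- synth_generate(synth_preset("separable", n_sequences = n_seq,
                                   length = len, D = D, seed = seed))
  g$data
}
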