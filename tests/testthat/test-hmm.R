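test_that("random initialization is row-stochastic and seed-deterministic", {
  h <- hmm_init(3, 5, seed = 42)
  expect_lt(max(abs(rowSums(h$A) - 1)), 1e-12)
  expect_lt(max(abs(rowSums(h$E) - 1)), 1e-12)
  expect_lt(abs(sum(h$pi) - 1), 1e-12)
  expect_true(all(h$A >= 0 & h$A <= 1))

  expect_identical(hmm_init(80, 5, seed = 0), hmm_init(80, 5, seed = 0))

  h1 <- hmm_init(1, 5, seed = 1)
  expect_equal(h1$A, matrix(1), ignore_attr = TRUE)
  expect_equal(h1$pi, 1)

  expect_error(hmm_init(0, 5), "N")
  expect_error(hmm_init(2, 1), "L")
})

test_that("forward-backward matches closed forms in degenerate cases", {
  # single state: gamma is all ones, loglik factorizes over emissions
  h1 <- hmm_init(1, 4, seed = 3)
  y <- c(1L, 3L, 2L, 3L)
  fb <- hmm_forward_backward(h1, y)
  expect_equal(as.vector(fb$gamma), rep(1, 4))
  expect_equal(fb$loglik, sum(log(h1$E[1, y])), tolerance = 1e-12)

  # uniform everything: loglik = T * log(1/L)
  hu <- structure(list(N = 2L, L = 5L, pi = c(.5, .5),
                       A = matrix(.5, 2, 2), E = matrix(.2, 2, 5)),
                  class = "cat_hmm")
  fbu <- hmm_forward_backward(hu, c(1L, 4L, 2L))
  expect_equal(fbu$loglik, 3 * log(1 / 5), tolerance = 1e-12)

  expect_error(hmm_forward_backward(h1, integer(0)), "empty")
  expect_error(hmm_forward_backward(h1, c(1L, 9L)), "1..4")
})

test_that("forward-backward agrees with the all-paths enumeration oracle", {
  worked <- structure(list(N = 2L, L = 2L, pi = c(0.6, 0.4),
                           A = matrix(c(0.7, 0.4, 0.3, 0.6), 2, 2),
                           E = matrix(c(0.9, 0.2, 0.1, 0.8), 2, 2)),
                      class = "cat_hmm")
  y <- c(1L, 2L, 2L, 1L)
  fb <- hmm_forward_backward(worked, y)
  bf <- bf_forward_backward(worked, y)
  expect_lt(max(abs(fb$gamma - bf$gamma)), 1e-10)
  expect_lt(abs(fb$loglik - bf$loglik), 1e-10)

  # posterior decoding equals the argmax of the oracle gammas
  expect_identical(hmm_decode(worked, y),
                   as.integer(apply(bf$gamma, 1, which.max)))

  set.seed(99)
  for (i in 1:20) {
    inst <- random_hmm_instance(N = sample(2:3, 1), L = sample(2:4, 1),
                                Tn = sample(2:6, 1))
    fb <- hmm_forward_backward(inst$params, inst$y)
    bf <- bf_forward_backward(inst$params, inst$y)
    expect_lt(max(abs(fb$gamma - bf$gamma)), 1e-10)
    expect_lt(abs(fb$loglik - bf$loglik), 1e-10)
  }
})

test_that("scaling keeps long sequences from underflowing", {
  set.seed(5)
  inst <- random_hmm_instance(3, 5, 1000)
  fb <- hmm_forward_backward(inst$params, inst$y)
  expect_true(is.finite(fb$loglik))
  expect_lt(fb$loglik, 0)
  expect_lt(max(abs(rowSums(fb$gamma) - 1)), 1e-9)
})

test_that("Baum-Welch: closed-form single-state M-step and EM monotonicity", {
  # N = 1: the fitted emission row is the empirical label frequency
  y <- c(rep(1L, 3), rep(2L, 7))
  fit <- hmm_fit(hmm_init(1, 2, seed = 2), y, max_iter = 2)
  expect_equal(as.vector(fit$params$E), c(0.3, 0.7), tolerance = 1e-12)

  set.seed(7)
  for (i in 1:15) {
    inst <- random_hmm_instance(N = sample(2:3, 1), L = sample(2:4, 1),
                                Tn = 30)
    fit <- hmm_fit(inst$params, inst$y, max_iter = 15, tol = 0)
    expect_true(all(diff(fit$loglik_trace) >= -1e-8))
    expect_lt(max(abs(rowSums(fit$params$A) - 1)), 1e-9)
    expect_lt(max(abs(rowSums(fit$params$E) - 1)), 1e-9)
  }
})

test_that("Baum-Welch recovers a well-separated generating HMM", {
  truth <- structure(list(
    N = 3L, L = 5L, pi = c(1, 1, 1) / 3,
    A = matrix(c(0.8, 0.1, 0.1,
                 0.1, 0.8, 0.1,
                 0.1, 0.1, 0.8), 3, 3, byrow = TRUE),
    E = matrix(c(0.90, 0.05, 0.01, 0.02, 0.02,
                 0.02, 0.05, 0.90, 0.01, 0.02,
                 0.02, 0.01, 0.02, 0.05, 0.90), 3, 5, byrow = TRUE)),
    class = "cat_hmm")
  ys <- hmm_simulate(truth, rep(200L, 20), seed = 0)
  fit <- hmm_fit_restarts(ys, 3, 5, restarts = 5, seed = 0, max_iter = 100)
  tv <- match_and_tv(truth, fit$params)
  expect_true(all(tv <= 0.1))

  # consistency: more data gives a tighter estimate
  ys_small <- hmm_simulate(truth, rep(200L, 2), seed = 1)
  fit_small <- hmm_fit_restarts(ys_small, 3, 5, restarts = 5, seed = 0,
                                max_iter = 100)
  expect_lte(mean(tv), mean(match_and_tv(truth, fit_small$params)) + 0.02)
})

test_that("posterior decoding breaks exact ties toward the smaller state", {
  # perfectly symmetric two-state model: gamma rows are exactly (0.5, 0.5)
  sym <- structure(list(N = 2L, L = 2L, pi = c(.5, .5),
                        A = matrix(.5, 2, 2),
                        E = matrix(c(.5, .5, .5, .5), 2, 2)),
                   class = "cat_hmm")
  expect_identical(hmm_decode(sym, c(1L, 2L, 1L)), rep(1L, 3))
  expect_identical(hmm_decode(hmm_init(1, 3, seed = 1), c(1L, 2L)),
                   rep(1L, 2))
})
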