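test_that("PER counts mismatches at the time-step level", {
  expect_equal(per(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(per(c(1, 1), c(2, 2)), 100)
  expect_equal(per(c(1, 2, 1, 2), c(1, 2, 2, 2)), 25)
  # pooling weights sequences by their length
  expect_equal(per(list(c(1, 2), c(1, 1, 1, 1, 1, 1)),
                   list(c(2, 1), c(1, 1, 1, 1, 1, 1))), 25)
  expect_error(per(c(1, 2), c(1, 2, 3)), "lengths")
  expect_error(per(list(c(1, 2)), list(c(1), c(2))), "numbers of sequences")
})

test_that("confusion matrix totals and PER identity", {
  y <- list(c(1L, 2L, 3L), c(3L, 3L, 1L))
  p <- list(c(1L, 3L, 3L), c(3L, 1L, 1L))
  m <- confusion_matrix(y, p, L = 3)
  expect_identical(sum(m), 6L)
  expect_identical(m[2, 3], 1L)
  expect_equal(100 * (1 - sum(diag(m)) / sum(m)), per(y, p))
})

test_that("the memoryless baseline learns separable data", {
  g <- synth_generate(synth_preset("separable", n_sequences = 15,
                                   length = 60, D = 8, seed = 2))
  sp <- split_holdout(g$data, 0.2, seed = 2)
  ctrl <- tdnn_control(batch_size = 128, epochs = 15, seed = 2)
  bl <- memoryless_fit(sp$train, ctrl)
  expect_lt(evaluate_memoryless(bl, sp$test), 5)
  # agreement with an established multinomial fit on the same data
  skip_if_not_installed("nnet")
  f <- do.call(rbind, lapply(sp$train$sequences, `[[`, "f"))
  y <- factor(unlist(lapply(sp$train$sequences, `[[`, "y")))
  mn <- nnet::multinom(y ~ f, trace = FALSE, maxit = 200)
  ft <- do.call(rbind, lapply(sp$test$sequences, `[[`, "f"))
  yt <- unlist(lapply(sp$test$sequences, `[[`, "y"))
  mn_per <- 100 * mean(as.integer(as.character(
    predict(mn, data.frame(f = I(ft))))) != yt)
  expect_lt(abs(mn_per - evaluate_memoryless(bl, sp$test)), 3)
})

test_that("baseline training is seed-deterministic", {
  g <- synth_generate(synth_preset("overlapping", n_sequences = 4,
                                   length = 30, D = 4, seed = 3))
  ctrl <- tdnn_control(batch_size = 32, epochs = 4, seed = 9)
  a <- memoryless_fit(g$data, ctrl)
  b <- memoryless_fit(g$data, ctrl)
  expect_identical(a$W, b$W)
  expect_identical(a$loss_trace, b$loss_trace)
})

test_that("hidden-state ablation returns one deterministic record per run", {
  g <- synth_generate(synth_preset("separable", n_sequences = 4,
                                   length = 20, D = 3, seed = 4))
  ctrl <- tdnn_control(batch_size = 64, epochs = 3, seed = 1)
  ab <- ablate_hidden_states(g$data, Ns = c(2L, 4L), repeats = 2,
                             seed = 1, hidden_dim = 8, control = ctrl,
                             hmm_max_iter = 5)
  expect_s3_class(ab, "dtmn_ablation")
  expect_identical(nrow(ab), 4L)
  expect_true(all(ab$per >= 0 & ab$per <= 100))
  expect_identical(nrow(attr(ab, "summary")), 2L)

  ab2 <- ablate_hidden_states(g$data, Ns = c(2L, 4L), repeats = 2,
                              seed = 1, hidden_dim = 8, control = ctrl,
                              hmm_max_iter = 5)
  expect_identical(ab$per, ab2$per)

  one <- ablate_hidden_states(g$data, Ns = 3L, repeats = 1, seed = 2,
                              hidden_dim = 8, control = ctrl,
                              hmm_max_iter = 5)
  expect_identical(nrow(one), 1L)
  expect_error(ablate_hidden_states(g$data, Ns = integer(0)), "empty")
})

test_that("context ablation shares the HMM stage within a repeat", {
  g <- synth_generate(synth_preset("persistent", n_sequences = 4,
                                   length = 20, D = 3, seed = 5))
  ctrl <- tdnn_control(batch_size = 64, epochs = 3, seed = 1)
  ab <- ablate_contexts(g$data, variants = c("tdnn1", "tdnn4"),
                        repeats = 2, seed = 3, n_hidden = 4,
                        hidden_dim = 8, control = ctrl, hmm_max_iter = 5)
  expect_identical(nrow(ab), 4L)
  expect_setequal(unique(ab$setting), c("tdnn1", "tdnn4"))
  # same repeat, different variants: identical HMM stage log-likelihood
  by_rep <- split(ab$hmm_loglik, ab$rep)
  for (h in by_rep) expect_identical(h[1], h[2])
  expect_error(ablate_contexts(g$data, variants = "tdnnX"),
               "unknown context preset")
})
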