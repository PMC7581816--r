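test_that("context presets encode the published offset sets", {
  c4 <- tdnn_context("tdnn4")
  expect_identical(c4$network, -5:-1)
  expect_identical(c4$l1, -3:-1)
  expect_identical(c4$l2, c(-3L, -1L))
  expect_identical(c4$l3, -1L)
  expect_identical(c4$window, 5L)
  expect_identical(tdnn_context("tdnn1")$network, -1L)
  expect_identical(tdnn_context("tdnn6")$l2, c(-9L, -5L, -1L))
  expect_error(tdnn_context("tdnn7"), "unknown context preset")
  expect_error(tdnn_context("custom", network = c(-2, -1), l1 = -1, l2 = 0),
               "strictly negative")
  expect_error(tdnn_context("custom", network = -1, l1 = -2, l2 = -1),
               "inside the network context")
})

test_that("alpha encoding is one-hot with all-zero boundary padding", {
  expect_identical(alpha_encode(1, 3), c(1, 0, 0))
  expect_identical(alpha_encode(3, 3), c(0, 0, 1))
  expect_identical(alpha_encode(NA, 3), c(0, 0, 0))
  expect_error(alpha_encode(4, 3), "outside")
  expect_error(alpha_encode(0, 3), "outside")
})

test_that("softmax is exact on closed forms and stable on huge logits", {
  expect_equal(softmax(c(0, 0, 0)), rep(1 / 3, 3))
  expect_equal(softmax(c(log(2), 0, 0)), c(0.5, 0.25, 0.25),
               tolerance = 1e-12)
  p <- softmax(c(1000, 0))
  expect_true(all(is.finite(p)))
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_gt(p[1], 1 - 1e-12)
  expect_error(softmax(c(Inf, 0)), "non-finite")
})

test_that("forward pass sums to one, is deterministic, uniform at zero", {
  ctx <- tdnn_context("tdnn4")
  net <- dtmn:::.tdnn_init(ctx, n_states = 6, D = 4, hidden_dim = 8,
                           seed = 1)
  f <- c(0.3, -1, 2, 0.5)
  p <- tdnn_forward(net, c(NA, NA, 1, 5, 2), f)
  expect_length(p, 6)
  expect_equal(sum(p), 1, tolerance = 1e-9)
  expect_true(all(p >= 0))
  expect_identical(p, tdnn_forward(net, c(NA, NA, 1, 5, 2), f))

  # all-zero weights with identity batch norm give the uniform distribution
  z <- net
  z$theta <- lapply(z$theta, function(x) 0 * x)
  pz <- tdnn_forward(z, c(1, 2, 3, 4, 5), f)
  expect_equal(pz, rep(1 / 6, 6), tolerance = 1e-12)

  expect_error(tdnn_forward(net, c(1, 2), f), "window")
  expect_error(tdnn_forward(net, c(NA, NA, 1, 5, 2), c(1, 2)), "dimension")
})

test_that("training is seed-deterministic and a zero learning rate is a no-op", {
  set.seed(2)
  n <- 30
  ex <- list(Q = matrix(sample(c(NA, 1:3), n * 5, TRUE), n),
             F = matrix(rnorm(n * 2), n),
             target = sample(3, n, TRUE))
  ctx <- tdnn_context("tdnn4")
  ctrl <- tdnn_control(batch_size = 8, epochs = 3, seed = 7)
  a <- tdnn_fit(ex, ctx, 3, ctrl, hidden_dim = 6)
  b <- tdnn_fit(ex, ctx, 3, ctrl, hidden_dim = 6)
  expect_identical(a$theta, b$theta)
  expect_identical(a$loss_trace, b$loss_trace)

  ctrl0 <- tdnn_control(batch_size = 8, epochs = 3, lr = 0, seed = 7)
  frozen <- tdnn_fit(ex, ctx, 3, ctrl0, hidden_dim = 6)
  init <- dtmn:::.tdnn_init(ctx, 3, 2, hidden_dim = 6, seed = 7)
  expect_identical(frozen$theta, init$theta)

  expect_error(tdnn_fit(list(Q = ex$Q, F = ex$F,
                             target = rep(9L, n)), ctx, 3, ctrl, 6),
               "targets")
})

test_that("SGD drives the loss down and can separate an easy 2-class task", {
  # 40 linearly separable examples, no temporal signal in the windows
  set.seed(3)
  n <- 40
  tg <- rep(1:2, each = n / 2)
  F <- matrix(rnorm(n * 3, sd = 0.3), n) + 3 * (tg == 2)
  ex <- list(Q = matrix(NA_integer_, n, 1), F = F, target = tg)
  ctx <- tdnn_context("tdnn1")
  net <- tdnn_fit(ex, ctx, 2,
                  tdnn_control(batch_size = 10, epochs = 50, seed = 1),
                  hidden_dim = 8)
  expect_true(all(is.finite(net$loss_trace)))
  expect_lt(net$loss_trace[50], net$loss_trace[1])
  pred <- vapply(seq_len(n), function(i)
    which.max(tdnn_forward(net, NA, F[i, ])), integer(1))
  expect_identical(pred, tg)
})

test_that("batch-norm running moments freeze inference", {
  # same input twice through infer mode after training: identical output,
  # and train-mode batch statistics do not leak into inference
  set.seed(4)
  n <- 24
  ex <- list(Q = matrix(sample(1:4, n * 1, TRUE), n),
             F = matrix(rnorm(n * 2), n),
             target = sample(4, n, TRUE))
  ctx <- tdnn_context("tdnn1")
  net <- tdnn_fit(ex, ctx, 4, tdnn_control(batch_size = 6, epochs = 2,
                                           seed = 9), hidden_dim = 5)
  batch <- dtmn:::.tdnn_batch_forward(net, ex$Q[1:6, , drop = FALSE],
                                      ex$F[1:6, , drop = FALSE],
                                      mode = "infer")$prob
  single <- tdnn_forward(net, ex$Q[1, ], ex$F[1, ])
  expect_equal(batch[1, ], single, tolerance = 1e-12)
})
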