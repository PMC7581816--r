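test_that("transition counting matches hand enumeration", {
  # angry, angry, high_stress, angry
  ch <- chain_fit(list(c(1L, 1L, 2L, 1L)), emotion_alphabet())
  expect_identical(ch$counts["angry", "angry"], 1L)
  expect_identical(ch$counts["angry", "high_stress"], 1L)
  expect_identical(ch$counts["high_stress", "angry"], 1L)
  expect_identical(sum(ch$counts), 3L)
  expect_equal(unname(ch$P["angry", ]), c(0.5, 0.5, 0, 0, 0))
  expect_equal(unname(ch$P["high_stress", ]), c(1, 0, 0, 0, 0))
  # unobserved source states fall back to the uniform row
  expect_equal(unname(ch$P["neutral", ]), rep(0.2, 5))
  expect_equal(transition_prob(ch, "angry", "high_stress"), 0.5)
  expect_equal(transition_prob(ch, 1, 2), 0.5)
  expect_error(transition_prob(ch, "bored", 1), "unknown state")
  expect_error(transition_prob(ch, 0, 1), "outside")
})

test_that("rows are stochastic and count conservation holds", {
  set.seed(21)
  for (i in 1:5) {
    seqs <- lapply(1:4, function(j) sample.int(5, sample(2:40, 1), TRUE))
    ch <- chain_fit(seqs, emotion_alphabet())
    expect_lt(max(abs(rowSums(ch$P) - 1)), 1e-12)
    expect_true(all(ch$P >= 0))
    expect_identical(sum(ch$counts),
                     sum(vapply(seqs, length, integer(1))) - 4L)
  }
})

test_that("transitions never pool across sequence boundaries", {
  ch <- chain_fit(list(c(1L, 2L), c(2L, 1L)), emotion_alphabet())
  expect_identical(ch$counts["high_stress", "high_stress"], 0L)
  expect_identical(sum(ch$counts), 2L)

  # constant sequence: only the self transition is observed
  cc <- chain_fit(list(c(3L, 3L, 3L)), emotion_alphabet())
  expect_equal(unname(cc$P["low_stress", "low_stress"]), 1)

  expect_error(chain_fit(list(1L, 2L), emotion_alphabet()),
               "no transitions")
})

test_that("zero-row rule and smoothing options behave as documented", {
  ch_self <- chain_fit(list(c(1L, 2L, 1L)), emotion_alphabet(),
                       zero_row_rule = "self_loop")
  expect_equal(unname(ch_self$P["soft", "soft"]), 1)
  ch_sm <- chain_fit(list(c(1L, 2L, 1L)), emotion_alphabet(),
                     smooth_k = 1)
  expect_true(all(ch_sm$P > 0))
  expect_lt(max(abs(rowSums(ch_sm$P) - 1)), 1e-12)
})

test_that("stationary distribution solves the balance equations", {
  mk_chain <- function(P, labels) {
    structure(list(alphabet = emotion_alphabet(labels),
                   counts = matrix(0L, nrow(P), ncol(P)), P = P,
                   group = NA_character_, n_transitions = 0L,
                   zero_row_rule = "uniform", smooth_k = 0),
              class = "emotion_chain")
  }
  sym <- mk_chain(matrix(0.5, 2, 2), c("a", "b"))
  expect_equal(unname(stationary_distribution(sym)), c(0.5, 0.5),
               tolerance = 1e-10)

  two <- mk_chain(matrix(c(0.9, 0.2, 0.1, 0.8), 2, 2), c("a", "b"))
  expect_equal(unname(stationary_distribution(two)), c(2 / 3, 1 / 3),
               tolerance = 1e-10)

  expect_error(stationary_distribution(mk_chain(diag(2), c("a", "b"))),
               "reducible")
  flip <- mk_chain(matrix(c(0, 1, 1, 0), 2, 2), c("a", "b"))
  expect_error(stationary_distribution(flip), "periodic")
})

test_that("estimation is consistent as transitions accumulate", {
  P_true <- dtmn:::.persistent_chain(5, 0.7, bias_state = 2L)
  tv_at <- function(n_trans, seed) {
    seqs <- chain_simulate(P_true, n_seq = n_trans / 100, len = 101,
                           seed = seed)
    ch <- chain_fit(seqs, emotion_alphabet())
    max(apply(abs(ch$P - P_true), 1, sum) / 2)
  }
  tv2k <- tv_at(2000, seed = 5)
  tv20k <- tv_at(20000, seed = 5)
  expect_lt(tv20k, tv2k)
  expect_lt(tv20k, 0.05)
})

test_that("chains round-trip through JSON and split by group", {
  g <- synth_generate(synth_preset("persistent", n_sequences = 3,
                                   length = 40, D = 3, seed = 2))
  chains <- chain_by_group(g$data)
  expect_setequal(names(chains), c("M", "F"))
  tf <- withr::local_tempfile(fileext = ".json")
  write_chains(chains, tf, source_labels = "gold")
  back <- read_chains(tf)
  expect_equal(back$M$P, chains$M$P, tolerance = 1e-15)
  expect_equal(back$F$counts, chains$F$counts, ignore_attr = TRUE)
})
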