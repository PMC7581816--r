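#' Configuration for the synthetic sequence generator
#'
#' The generator emulates the structure of labeled stress-speech embedding
#' data: per group, label sequences follow a ground-truth 5-state Markov
#' chain, and each step's feature vector is drawn from a Gaussian centred on
#' the mean of its (pre-noise) label.  Class separation, chain persistence
#' and label noise are independent knobs, so feature overlap and temporal
#' structure can be varied separately.
#'
#' @param n_sequences sequences generated per group (default 25).
#' @param length sequence length: a single value or a `c(min, max)` range
#'   sampled uniformly per sequence (default 200).
#' @param chains named list of row-stochastic ground-truth transition
#'   matrices, one per group.  Default: two persistent chains ("M", "F")
#'   with identical 0.9 diagonals but opposite off-diagonal tendencies
#'   (toward angry vs toward soft).
#' @param init named list of initial label distributions per group (default
#'   uniform).
#' @param D feature dimension (default 8).
#' @param separation distance scale between class mean vectors (> 0;
#'   default 1.5, an overlapping regime).
#' @param noise_rate probability that an emitted label is flipped uniformly
#'   to another label; features always follow the true label.  In `[0, 0.5)`.
#' @param alphabet the label alphabet (default canonical 5 emotions).
#' @param seed RNG seed.
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(n_sequences = 25L, length = 200L, chains = NULL,
                         init = NULL, D = 8L, separation = 1.5,
                         noise_rate = 0, alphabet = emotion_alphabet(),
                         seed = 1L) {
  if (!inherits(alphabet, "emotion_alphabet"))
    alphabet <- emotion_alphabet(alphabet)
  L <- base::length(alphabet)
  if (is.null(chains))
    chains <- list(M = .persistent_chain(L, 0.9, bias_state = 1L),
                   F = .persistent_chain(L, 0.9, bias_state = L))
  problems <- character(0)
  if (n_sequences < 1L) problems <- c(problems, "n_sequences must be >= 1")
  if (!base::length(length) %in% 1:2 || any(length < 1L))
    problems <- c(problems, "length must be a positive value or range")
  if (base::length(length) == 2L && length[1] > length[2])
    problems <- c(problems, "length range must be increasing")
  if (D < 1L) problems <- c(problems, "D must be >= 1")
  if (separation <= 0) problems <- c(problems, "separation must be > 0")
  if (noise_rate < 0 || noise_rate >= 0.5)
    problems <- c(problems, "noise_rate must be in [0, 0.5)")
  for (g in names(chains)) {
    P <- chains[[g]]
    if (!is.matrix(P) || nrow(P) != L || ncol(P) != L)
      problems <- c(problems, paste0("chain '", g, "' is not ", L, "x", L))
    else if (any(P < 0) || max(abs(rowSums(P) - 1)) > 1e-9)
      problems <- c(problems, paste0("chain '", g, "' is not row-stochastic"))
  }
  if (is.null(init))
    init <- stats::setNames(rep(list(rep(1 / L, L)), base::length(chains)),
                            names(chains))
  for (g in names(init)) {
    p <- init[[g]]
    if (base::length(p) != L || any(p < 0) || abs(sum(p) - 1) > 1e-9)
      problems <- c(problems, paste0("init '", g, "' is not a distribution"))
  }
  if (base::length(problems))
    stop("invalid synthetic config:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  structure(list(n_sequences = as.integer(n_sequences),
                 length = as.integer(length),
                 chains = chains, init = init, D = as.integer(D),
                 separation = separation, noise_rate = noise_rate,
                 alphabet = alphabet, seed = as.integer(seed)),
            class = "synth_config")
}

# diagonal-dominant chain: diagonal `diag_p`, remaining mass biased toward
# `bias_state` (weight 2 vs 1 elsewhere)
.persistent_chain <- function(L, diag_p, bias_state = 1L) {
  P <- matrix(0, L, L)
  for (i in seq_len(L)) {
    w <- rep(1, L); w[bias_state] <- 2; w[i] <- 0
    P[i, ] <- (1 - diag_p) * w / sum(w)
    P[i, i] <- diag_p
  }
  P
}

#' Named generator presets
#'
#' * `separable`: large class separation (4.0), mild persistence
#'   (diagonal 0.6) — features alone nearly determine the label.
#' * `overlapping`: small separation (1.5), mild persistence — features are
#'   ambiguous.
#' * `persistent`: small separation with strongly diagonal chains (every
#'   diagonal entry 0.9) — temporal context is informative, mirroring the
#'   observation that emotions rarely change over short spans.
#' * `iid`: uniform transition matrices (every entry 1/5) — no temporal
#'   signal at all.
#'
#' @param name preset name.
#' @param ... overrides passed on to [synth_config()] (e.g. `n_sequences`,
#'   `length`, `seed`).
#' @return A `synth_config`.
#' @export
synth_preset <- function(name = c("separable", "overlapping", "persistent",
                                  "iid"), ...) {
  if (!is.character(name) || length(name) != 1L ||
      !name %in% c("separable", "overlapping", "persistent", "iid"))
    stop("unknown preset '", paste(name, collapse = ","),
         "'; known: separable, overlapping, persistent, iid", call. = FALSE)
  L <- 5L
  mild_M <- .persistent_chain(L, 0.6, bias_state = 1L)
  mild_F <- .persistent_chain(L, 0.6, bias_state = L)
  args <- switch(name,
    separable = list(separation = 4.0,
                     chains = list(M = mild_M, F = mild_F)),
    overlapping = list(separation = 1.5,
                       chains = list(M = mild_M, F = mild_F)),
    persistent = list(separation = 1.5,
                      chains = list(M = .persistent_chain(L, 0.9, 1L),
                                    F = .persistent_chain(L, 0.9, L))),
    iid = list(separation = 1.5,
               chains = list(M = matrix(1 / L, L, L),
                             F = matrix(1 / L, L, L))))
  do.call(synth_config, utils::modifyList(args, list(...)))
}

# deterministic class means: label l sits at separation * e_{(l-1) mod D + 1}
.class_means <- function(L, D, separation) {
  mu <- matrix(0, L, D)
  for (l in seq_len(L)) mu[l, ((l - 1L) %% D) + 1L] <- separation
  mu
}

#' Generate a synthetic sequence set
#'
#' Per sequence: the initial label is drawn from the group's initial
#' distribution, subsequent labels follow the group's ground-truth chain,
#' features are drawn from a unit-variance Gaussian centred on the pre-noise
#' label's mean vector, and the observed label is flipped uniformly to
#' another label with probability `noise_rate`.  Fully reproducible from the
#' config seed.
#'
#' @param cfg a [synth_config()].
#' @return List with `data` (a [sequence_set()]) and `truth` (list with the
#'   config, the pre-noise `true_labels` per sequence, and the per-group
#'   `chains`).
#' @export
synth_generate <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(cfg$seed)
  L <- length(cfg$alphabet)
  mu <- .class_means(L, cfg$D, cfg$separation)
  seqs <- list()
  true_labels <- list()
  for (g in names(cfg$chains)) {
    P <- cfg$chains[[g]]
    init <- cfg$init[[g]]
    for (i in seq_len(cfg$n_sequences)) {
      Tn <- if (length(cfg$length) == 2L)
        sample(cfg$length[1]:cfg$length[2], 1L) else cfg$length
      y <- integer(Tn)
      y[1] <- sample.int(L, 1L, prob = init)
      if (Tn > 1L) for (t in 2:Tn)
        y[t] <- sample.int(L, 1L, prob = P[y[t - 1L], ])
      f <- mu[y, , drop = FALSE] +
        matrix(stats::rnorm(Tn * cfg$D), Tn, cfg$D)
      y_obs <- y
      if (cfg$noise_rate > 0) {
        flip <- stats::runif(Tn) < cfg$noise_rate
        if (any(flip)) {
          y_obs[flip] <- vapply(y[flip], function(l) {
            cand <- setdiff(seq_len(L), l)
            cand[sample.int(L - 1L, 1L)]
          }, integer(1))
        }
      }
      id <- sprintf("%s%03d", tolower(g), i)
      seqs[[length(seqs) + 1L]] <- list(id = id, group = g,
                                        y = y_obs, f = f)
      true_labels[[id]] <- y
    }
  }
  data <- sequence_set(seqs, cfg$alphabet)
  list(data = data,
       truth = list(config = cfg, true_labels = true_labels,
                    chains = cfg$chains))
}
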