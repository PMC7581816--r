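#' Estimate a finite Markov chain from label sequences
#'
#' Counts consecutive within-sequence transitions (never across sequence
#' boundaries) and normalizes each row to a probability distribution,
#' yielding the maximum-likelihood transition matrix `P` with
#' `P[i, j] = P(X_{t+1} = j | X_t = i)`.  Rows of a state never observed as
#' a source are filled per `zero_row_rule` so `P` stays row-stochastic.
#'
#' @param x a [sequence_set()] (its labels are used) or a list of integer
#'   label vectors.
#' @param alphabet an [emotion_alphabet()]; taken from `x` when it is a
#'   sequence set.
#' @param zero_row_rule `"uniform"` (default) or `"self_loop"` fill for
#'   zero-count rows.
#' @param smooth_k optional add-k smoothing constant (default 0: exact
#'   zero counts give exact zero probabilities).
#' @param group optional group tag recorded in the result.
#' @return An object of class `emotion_chain`: list with `alphabet`,
#'   `counts` (n x n integer), `P` (n x n row-stochastic), `group`,
#'   `n_transitions`.
#' @export
chain_fit <- function(x, alphabet = NULL,
                      zero_row_rule = c("uniform", "self_loop"),
                      smooth_k = 0, group = NA_character_) {
  zero_row_rule <- match.arg(zero_row_rule)
  if (inherits(x, "sequence_set")) {
    alphabet <- x$alphabet
    seqs <- label_sequences(x)
  } else {
    if (is.null(alphabet))
      stop("alphabet required when x is a list of label vectors",
           call. = FALSE)
    if (!inherits(alphabet, "emotion_alphabet"))
      alphabet <- emotion_alphabet(alphabet)
    seqs <- if (is.list(x)) x else list(x)
  }
  n <- length(alphabet)
  counts <- matrix(0L, n, n,
                   dimnames = list(from = as.character(alphabet),
                                   to = as.character(alphabet)))
  any_trans <- FALSE
  for (y in seqs) {
    y <- as.integer(y)
    if (anyNA(y) || (length(y) && (min(y) < 1L || max(y) > n)))
      stop("label sequence contains values outside the alphabet",
           call. = FALSE)
    if (length(y) < 2L) next
    any_trans <- TRUE
    from <- y[-length(y)]; to <- y[-1L]
    for (t in seq_along(from))
      counts[from[t], to[t]] <- counts[from[t], to[t]] + 1L
  }
  if (!any_trans)
    stop("no transitions: every sequence has length < 2", call. = FALSE)
  P <- counts + smooth_k
  rs <- rowSums(P)
  zero <- rs == 0
  P <- P / ifelse(rs == 0, 1, rs)
  if (any(zero)) {
    for (i in which(zero)) {
      if (zero_row_rule == "uniform") P[i, ] <- 1 / n
      else P[i, i] <- 1
    }
  }
  structure(list(alphabet = alphabet, counts = counts, P = P,
                 group = group, n_transitions = sum(counts),
                 zero_row_rule = zero_row_rule, smooth_k = smooth_k),
            class = "emotion_chain")
}

#' Estimate one chain per group
#'
#' Splits a sequence set by group tag and fits a Markov chain to each part,
#' the idiom used to contrast e.g. male and female transition structure.
#'
#' @param data a [sequence_set()].
#' @param ... passed to [chain_fit()].
#' @return Named list of `emotion_chain` objects.
#' @export
chain_by_group <- function(data, ...) {
  parts <- split_by_group(data)
  out <- lapply(names(parts), function(g)
    chain_fit(parts[[g]], group = g, ...))
  names(out) <- names(parts)
  out
}

#' One-step transition probability
#'
#' @param model an `emotion_chain`.
#' @param i,j source and destination states, as 1-based indices or label
#'   names.
#' @return `P[i, j]`.
#' @export
transition_prob <- function(model, i, j) {
  stopifnot(inherits(model, "emotion_chain"))
  ix <- .chain_state(model, i)
  jx <- .chain_state(model, j)
  model$P[ix, jx]
}

.chain_state <- function(model, s) {
  n <- length(model$alphabet)
  if (is.character(s)) {
    ix <- match(.resolve_aliases(s), as.character(model$alphabet))
    if (is.na(ix)) stop("unknown state '", s, "'", call. = FALSE)
    return(ix)
  }
  s <- as.integer(s)
  if (is.na(s) || s < 1L || s > n)
    stop("state index outside 1..", n, call. = FALSE)
  s
}

#' Stationary distribution of an estimated chain
#'
#' Solves for the unique left fixed vector `pi P = pi`, `sum(pi) = 1`.  The
#' chain must be irreducible and aperiodic; this is verified by graph
#' reachability and the cycle-gcd period before solving, and a reducible or
#' periodic chain is an error rather than a silent fallback.
#'
#' @param model an `emotion_chain`.
#' @return Named probability vector over the states.
#' @export
stationary_distribution <- function(model) {
  stopifnot(inherits(model, "emotion_chain"))
  P <- model$P
  n <- nrow(P)
  adj <- P > 0
  if (!.strongly_connected(adj))
    stop("chain is reducible: no unique stationary distribution",
         call. = FALSE)
  if (.chain_period(adj) > 1L)
    stop("chain is periodic (period ", .chain_period(adj),
         "): stationary limit does not exist", call. = FALSE)
  A <- rbind(t(P) - diag(n), rep(1, n))
  b <- c(rep(0, n), 1)
  piv <- qr.solve(A, b)
  piv[piv < 0 & piv > -1e-12] <- 0
  piv <- piv / sum(piv)
  if (max(abs(as.vector(piv %*% P) - piv)) > 1e-10)
    stop("stationary solve did not converge to tolerance", call. = FALSE)
  stats::setNames(piv, as.character(model$alphabet))
}

.strongly_connected <- function(adj) {
  n <- nrow(adj)
  reach_from <- function(a, s) {
    seen <- logical(n); seen[s] <- TRUE
    front <- s
    while (length(front)) {
      nxt <- unique(unlist(lapply(front, function(v) which(a[v, ]))))
      nxt <- nxt[!seen[nxt]]
      seen[nxt] <- TRUE
      front <- nxt
    }
    seen
  }
  all(reach_from(adj, 1L)) && all(reach_from(t(adj), 1L))
}

# period of an irreducible chain: gcd over edges of d[u] + 1 - d[v]
# for BFS levels d from an arbitrary root
.chain_period <- function(adj) {
  n <- nrow(adj)
  d <- rep(NA_integer_, n); d[1L] <- 0L
  front <- 1L
  while (length(front)) {
    nxt <- integer(0)
    for (v in front) for (w in which(adj[v, ])) if (is.na(d[w])) {
      d[w] <- d[v] + 1L
      nxt <- c(nxt, w)
    }
    front <- unique(nxt)
  }
  g <- 0L
  gcd2 <- function(a, b) if (b == 0L) a else gcd2(b, a %% b)
  for (v in seq_len(n)) for (w in which(adj[v, ]))
    g <- gcd2(g, abs(d[v] + 1L - d[w]))
  if (g == 0L) 1L else g
}

#' Simulate label sequences from a transition matrix
#'
#' @param P row-stochastic transition matrix.
#' @param n_seq number of sequences.
#' @param len sequence length.
#' @param init initial distribution (default uniform).
#' @param seed RNG seed.
#' @return List of integer label sequences.
#' @export
chain_simulate <- function(P, n_seq, len, init = NULL, seed = 1L) {
  n <- nrow(P)
  if (is.null(init)) init <- rep(1 / n, n)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  lapply(seq_len(n_seq), function(i) {
    y <- integer(len)
    y[1] <- sample.int(n, 1L, prob = init)
    if (len > 1L) for (t in 2:len)
      y[t] <- sample.int(n, 1L, prob = P[y[t - 1L], ])
    y
  })
}

#' @export
print.emotion_chain <- function(x, digits = 2, ...) {
  cat("Emotional state transition chain")
  if (!is.na(x$group)) cat(" [group: ", x$group, "]", sep = "")
  cat(" -- ", x$n_transitions, " observed transitions\n", sep = "")
  cat("Transition probabilities P(i -> j), rows = source state:\n")
  print(round(x$P, digits))
  invisible(x)
}

#' Write estimated chains to JSON
#'
#' @param chains a single `emotion_chain` or a named list of them (one per
#'   group, as from [chain_by_group()]).
#' @param path output file path.
#' @param source_labels `"predicted"` or `"gold"`: which labels the chains
#'   were estimated from, recorded in the file.
#' @return `path`, invisibly.
#' @export
write_chains <- function(chains, path, source_labels = "predicted") {
  if (inherits(chains, "emotion_chain")) chains <- list(chain = chains)
  obj <- list(format_version = .DTMN_FORMAT_VERSION, kind = "emotion_chains",
              source_labels = source_labels,
              alphabet = as.character(chains[[1]]$alphabet),
              groups = lapply(chains, function(ch)
                list(group = ch$group, counts = ch$counts, P = ch$P,
                     n_transitions = ch$n_transitions)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Read chains written by [write_chains()]
#'
#' @param path file path.
#' @return Named list of `emotion_chain` objects.
#' @export
read_chains <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$kind, "emotion_chains"))
    stop("not a chain file: ", path, call. = FALSE)
  alph <- emotion_alphabet(obj$alphabet)
  out <- lapply(obj$groups, function(g) {
    counts <- .as_matrix(g$counts)
    P <- .as_matrix(g$P)
    dimnames(counts) <- dimnames(P) <-
      list(from = as.character(alph), to = as.character(alph))
    structure(list(alphabet = alph, counts = counts, P = P,
                   group = if (is.null(g$group)) NA_character_ else g$group,
                   n_transitions = g$n_transitions,
                   zero_row_rule = "uniform", smooth_k = 0),
              class = "emotion_chain")
  })
  out
}
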