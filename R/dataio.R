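#' Emotion label alphabet
#'
#' Construct the ordered label alphabet used throughout the package.  The
#' canonical five-state alphabet orders the labels angry, high_stress,
#' low_stress, neutral, soft; index 1 is "angry" and index 5 is "soft" in
#' every interface.  `medium_stress` is accepted as an input alias for
#' `low_stress` when labels are parsed from files.
#'
#' @param labels character vector of unique label names, length >= 2.
#' @return An object of class `emotion_alphabet` (a character vector).
#' @export
#' @examples
#' emotion_alphabet()
#' emotion_alphabet(c("calm", "agitated"))
emotion_alphabet <- function(labels = c("angry", "high_stress", "low_stress",
                                        "neutral", "soft")) {
  labels <- as.character(labels)
  if (length(labels) < 2L)
    stop("an alphabet needs at least 2 labels", call. = FALSE)
  if (anyDuplicated(labels))
    stop("alphabet labels must be unique", call. = FALSE)
  if (any(!nzchar(labels)) || anyNA(labels))
    stop("alphabet labels must be non-empty strings", call. = FALSE)
  structure(labels, class = "emotion_alphabet")
}

.canonical_labels <- c("angry", "high_stress", "low_stress", "neutral", "soft")
.label_aliases <- c(medium_stress = "low_stress")

# map raw label strings to canonical names (alias resolution only)
.resolve_aliases <- function(x) {
  hit <- x %in% names(.label_aliases)
  x[hit] <- .label_aliases[x[hit]]
  x
}

#' @export
print.emotion_alphabet <- function(x, ...) {
  cat("Emotion alphabet (", length(x), " labels): ",
      paste(seq_along(x), unclass(x), sep = "=", collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Assemble and validate a sequence set
#'
#' A sequence set bundles labeled (or partially labeled) utterance-level time
#' series: each sequence carries an id, an optional group tag, a length-T
#' integer label vector `y` (NA marks an unlabeled step) indexing into the
#' shared alphabet, and a T x D feature matrix `f`.
#'
#' @param sequences list of sequences; each a list with elements `id`,
#'   `group` (string or NA), `y` (integer vector, NA allowed), `f` (numeric
#'   matrix with `length(y)` rows).
#' @param alphabet an [emotion_alphabet()].
#' @return An object of class `sequence_set` with elements `alphabet`, `D`,
#'   `sequences`.
#' @export
sequence_set <- function(sequences, alphabet) {
  if (!inherits(alphabet, "emotion_alphabet"))
    alphabet <- emotion_alphabet(alphabet)
  stopifnot(is.list(sequences))
  D <- NA_integer_
  L <- length(alphabet)
  for (s in sequences) {
    if (is.null(s$id) || !nzchar(s$id))
      stop("every sequence needs a non-empty id", call. = FALSE)
    if (!is.matrix(s$f) || !is.numeric(s$f))
      stop("sequence '", s$id, "': features must be a numeric matrix",
           call. = FALSE)
    if (nrow(s$f) != length(s$y))
      stop("sequence '", s$id, "': feature rows and label length differ",
           call. = FALSE)
    if (nrow(s$f) < 1L)
      stop("sequence '", s$id, "' is empty", call. = FALSE)
    if (is.na(D)) D <- ncol(s$f)
    if (ncol(s$f) != D)
      stop("sequence '", s$id, "': feature dimension ", ncol(s$f),
           " != shared dimension ", D, call. = FALSE)
    yy <- s$y[!is.na(s$y)]
    if (length(yy) && (any(yy < 1L) || any(yy > L)))
      stop("sequence '", s$id, "': label index outside alphabet 1..", L,
           call. = FALSE)
  }
  structure(list(alphabet = alphabet,
                 D = if (is.na(D)) 0L else as.integer(D),
                 sequences = sequences),
            class = "sequence_set")
}

#' @export
print.sequence_set <- function(x, ...) {
  Ts <- vapply(x$sequences, function(s) length(s$y), integer(1))
  cat("Sequence set: ", length(x$sequences), " sequences, ",
      sum(Ts), " steps, D = ", x$D, "\n", sep = "")
  print(x$alphabet)
  grp <- vapply(x$sequences, function(s)
    if (is.null(s$group) || is.na(s$group)) "ungrouped" else s$group,
    character(1))
  if (length(grp)) {
    tab <- table(grp)
    cat("Groups: ", paste(names(tab), tab, sep = "=", collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Read a tab-separated sequence table
#'
#' The expected format is tab-separated with a header row
#' `seq_id  group  t  label  feat_0 ... feat_{D-1}`.  Rows belonging to the
#' same `seq_id` must have contiguous time indices `t = 1..T` (in any row
#' order; rows are sorted).  An empty `label` cell marks an unlabeled step;
#' an empty `group` cell an ungrouped sequence.
#'
#' @param path file path.
#' @param alphabet optional [emotion_alphabet()].  When omitted the alphabet
#'   is inferred from the observed labels, ordered canonically when they are
#'   canonical emotion names and lexicographically otherwise.
#' @return A [sequence_set()].
#' @export
read_sequence_table <- function(path, alphabet = NULL) {
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           na.strings = NULL, quote = "")
  need <- c("seq_id", "group", "t", "label")
  if (!all(need %in% names(raw)))
    stop("sequence table must have columns ",
         paste(need, collapse = ", "), " and feat_* columns", call. = FALSE)
  featcols <- grep("^feat_[0-9]+$", names(raw), value = TRUE)
  if (length(featcols) == 0L)
    stop("sequence table has no feat_* columns", call. = FALSE)
  featcols <- featcols[order(as.integer(sub("^feat_", "", featcols)))]
  D <- length(featcols)

  if (nrow(raw) == 0L) {
    alph <- if (is.null(alphabet)) emotion_alphabet() else alphabet
    return(sequence_set(list(), alph))
  }

  tvals <- suppressWarnings(as.integer(raw$t))
  if (anyNA(tvals))
    stop("non-integer time index at data row ", which(is.na(tvals))[1],
         call. = FALSE)

  fmat <- matrix(NA_real_, nrow(raw), D)
  for (j in seq_len(D)) {
    cell <- raw[[featcols[j]]]
    v <- suppressWarnings(as.numeric(cell))
    bad <- which(is.na(v))
    if (length(bad))
      stop("non-numeric feature '", cell[bad[1]], "' in column ",
           featcols[j], " at data row ", bad[1], call. = FALSE)
    fmat[, j] <- v
  }

  labs_raw <- .resolve_aliases(raw$label)
  if (is.null(alphabet)) {
    obs <- unique(labs_raw[nzchar(labs_raw)])
    if (all(obs %in% .canonical_labels)) {
      obs <- .canonical_labels[.canonical_labels %in% obs]
    } else {
      obs <- sort(obs)
    }
    if (length(obs) < 2L)
      obs <- union(obs, .canonical_labels)[seq_len(max(2L, length(obs)))]
    alphabet <- emotion_alphabet(obs)
  } else if (!inherits(alphabet, "emotion_alphabet")) {
    alphabet <- emotion_alphabet(alphabet)
  }
  y_all <- match(labs_raw, unclass(alphabet))
  unknown <- which(nzchar(labs_raw) & is.na(y_all))
  if (length(unknown))
    stop("label '", labs_raw[unknown[1]], "' at data row ", unknown[1],
         " is not in the alphabet", call. = FALSE)

  ids <- raw$seq_id
  seqs <- list()
  for (id in unique(ids)) {
    idx <- which(ids == id)
    tt <- tvals[idx]
    if (anyDuplicated(tt))
      stop("duplicate (seq_id, t) pair: ('", id, "', ",
           tt[anyDuplicated(tt)], ")", call. = FALSE)
    ord <- order(tt)
    idx <- idx[ord]
    tt <- tt[ord]
    if (!identical(tt, seq_len(length(tt))))
      stop("sequence '", id, "': time indices are not contiguous 1..T ",
           "(saw ", paste(utils::head(tt, 6), collapse = ","),
           if (length(tt) > 6) ",..." else "", ")", call. = FALSE)
    grp <- unique(raw$group[idx])
    if (length(grp) > 1L)
      stop("sequence '", id, "' carries more than one group tag",
           call. = FALSE)
    grp <- if (nzchar(grp)) grp else NA_character_
    seqs[[length(seqs) + 1L]] <- list(
      id = id, group = grp,
      y = as.integer(y_all[idx]),
      f = fmat[idx, , drop = FALSE])
  }
  sequence_set(seqs, alphabet)
}

#' Write a sequence set as a tab-separated table
#'
#' Features are serialized with 17 significant digits so that
#' `read_sequence_table(write_sequence_table(x))` reproduces `x` exactly.
#'
#' @param data a [sequence_set()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sequence_table <- function(data, path) {
  stopifnot(inherits(data, "sequence_set"))
  D <- data$D
  header <- paste(c("seq_id", "group", "t", "label",
                    paste0("feat_", seq_len(max(D, 1L)) - 1L)),
                  collapse = "\t")
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(header, con)
  for (s in data$sequences) {
    Tn <- length(s$y)
    lab <- ifelse(is.na(s$y), "", unclass(data$alphabet)[s$y])
    grp <- if (is.null(s$group) || is.na(s$group)) "" else s$group
    feats <- apply(s$f, 1L, function(r)
      paste(sprintf("%.17g", r), collapse = "\t"))
    writeLines(paste(s$id, grp, seq_len(Tn), lab, feats, sep = "\t"), con)
  }
  invisible(path)
}

#' Split a sequence set by group tag
#'
#' Partitions the sequences by their group tag; sequences without a tag are
#' collected under the reserved key `"ungrouped"`.
#'
#' @param data a [sequence_set()].
#' @return Named list of [sequence_set()] objects, one per group.
#' @export
split_by_group <- function(data) {
  stopifnot(inherits(data, "sequence_set"))
  if (length(data$sequences) == 0L) return(structure(list(), names = character(0)))
  tags <- vapply(data$sequences, function(s)
    if (is.null(s$group) || is.na(s$group)) "ungrouped" else s$group,
    character(1))
  out <- list()
  for (g in unique(tags))
    out[[g]] <- sequence_set(data$sequences[tags == g], data$alphabet)
  out
}

#' Extract label sequences
#'
#' @param data a [sequence_set()].
#' @return List of integer label vectors (NA for unlabeled steps).
#' @export
label_sequences <- function(data) {
  stopifnot(inherits(data, "sequence_set"))
  lapply(data$sequences, `[[`, "y")
}

# ---- JSON model container ------------------------------------------------

.DTMN_FORMAT_VERSION <- "1.0"

.as_matrix <- function(x) {
  if (is.matrix(x)) x else do.call(rbind, lapply(x, as.numeric))
}

#' Serialize a fitted DTMN model to JSON
#'
#' Writes the bundled HMM, TDNN and context specification together with the
#' alphabet and a format-version field, at full floating-point precision.
#'
#' @param model a fitted [dtmn()] model.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dtmn <- function(model, path) {
  stopifnot(inherits(model, "dtmn"))
  obj <- list(
    format_version = .DTMN_FORMAT_VERSION,
    kind = "dtmn_model",
    alphabet = as.character(model$alphabet),
    D = model$D,
    hmm = list(N = model$hmm$N, L = model$hmm$L, pi = model$hmm$pi,
               A = model$hmm$A, E = model$hmm$E,
               loglik_trace = model$hmm_trace, n_iter = model$hmm_iter),
    ctx = list(name = model$ctx$name, network = model$ctx$network,
               l1 = model$ctx$l1, l2 = model$ctx$l2, l3 = model$ctx$l3),
    tdnn = .tdnn_pack(model$tdnn),
    config = model$config)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = FALSE)
  invisible(path)
}

#' Read a DTMN model from JSON
#'
#' @param path a file written by [write_dtmn()].
#' @return A fitted model of class `dtmn`.
#' @export
read_dtmn <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$kind, "dtmn_model"))
    stop("not a dtmn model file: ", path, call. = FALSE)
  hmm <- list(N = as.integer(obj$hmm$N), L = as.integer(obj$hmm$L),
              pi = as.numeric(obj$hmm$pi),
              A = .as_matrix(obj$hmm$A), E = .as_matrix(obj$hmm$E))
  class(hmm) <- "cat_hmm"
  ctx <- tdnn_context(obj$ctx$name)
  model <- list(hmm = hmm,
                hmm_trace = as.numeric(obj$hmm$loglik_trace),
                hmm_iter = as.integer(obj$hmm$n_iter),
                tdnn = .tdnn_unpack(obj$tdnn),
                ctx = ctx,
                alphabet = emotion_alphabet(obj$alphabet),
                D = as.integer(obj$D),
                config = obj$config)
  class(model) <- "dtmn"
  model
}
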