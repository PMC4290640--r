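# k-separated amino-acid pair (k-AAP) feature extraction and the baseline
# feature sets it is compared against.

#' Concatenate the evolutionary and structural probability blocks
#'
#' Builds Q = \[P | S\]: the 20 PSSM probability columns (canonical order)
#' followed by the secondary-structure columns (helix, strand, coil). With the
#' default 3-state structure block Q has 23 columns, and each row sums to 2
#' because both blocks are row-stochastic.
#'
#' @param profile A [protein_profile()].
#' @return A numeric L x (20 + s) matrix with named columns.
#' @export
build_Q <- function(profile) {
  Q <- cbind(profile$P, profile$S)
  colnames(Q) <- q_colnames(colnames(profile$S))
  Q
}

#' Pair features for a single separation k
#'
#' Computes the shifted pair-product matrix
#' `R_k(m, n) = sum_{i=1}^{L-k} Q[i, m] * Q[i+k, n]`
#' over all column pairs of the concatenated profile matrix, and its row-major
#' flattening `(R_k(1,1), R_k(1,2), ..., R_k(1,23), R_k(2,1), ..., R_k(23,23))`.
#' With 23 columns the flattened vector has 529 entries. When `L <= k` the sum
#' is empty and every entry is zero.
#'
#' @param Q Concatenated profile matrix from [build_Q()] (or any numeric
#'   matrix; the pair product is generic in the number of columns).
#' @param k Positive integer separation between the paired rows.
#' @return A list of class `pair_features` with elements `k`, `R` (the
#'   m x m matrix) and `flat` (named row-major vector of length m^2).
#' @export
kaap_single <- function(Q, k) {
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != round(k)) {
    abort_input("k must be a single integer >= 1 (got %s)", toString(k))
  }
  Q <- as.matrix(Q)
  L <- nrow(Q)
  m <- ncol(Q)
  if (L > k) {
    R <- crossprod(Q[seq_len(L - k), , drop = FALSE],
                   Q[seq_len(L - k) + k, , drop = FALSE])
  } else {
    R <- matrix(0, m, m)
  }
  dimnames(R) <- list(colnames(Q), colnames(Q))
  flat <- as.vector(t(R))  # row-major: m varies slowest
  if (!is.null(colnames(Q))) {
    grid <- expand.grid(n = colnames(Q), m = colnames(Q), stringsAsFactors = FALSE)
    names(flat) <- paste0("k", k, "_", grid$m, "_", grid$n)
  }
  structure(list(k = k, R = R, flat = flat), class = "pair_features")
}

#' Full k-AAP feature vector
#'
#' Concatenates the flattened pair-feature vectors for separations
#' k = 1..`k_max` in ascending order. At the defaults (23-column Q, k_max = 4)
#' the result has 4 x 529 = 2116 entries.
#'
#' @param Q Concatenated profile matrix from [build_Q()].
#' @param k_max Largest separation; defaults to 4, past which larger
#'   separations carry little pair correlation.
#' @return Named numeric vector of length `k_max * ncol(Q)^2`.
#' @export
kaap_full <- function(Q, k_max = 4L) {
  if (k_max < 1) abort_input("k_max must be >= 1")
  unlist(lapply(seq_len(k_max), function(k) kaap_single(Q, k)$flat))
}

#' Consensus sequence from the evolutionary profile
#'
#' Replaces each residue by the amino acid with the highest probability in
#' the PSSM row. Ties break to the lowest canonical column index.
#'
#' @param profile A [protein_profile()].
#' @return Amino-acid string of the same length as the input sequence.
#' @export
consensus_sequence <- function(profile) {
  paste(aa_order()[max.col(profile$P, ties.method = "first")], collapse = "")
}

#' Amino-acid composition and occurrence
#'
#' Counts each of the 20 standard amino acids in the sequence, in canonical
#' order. With `normalize = TRUE` counts are divided by the effective sequence
#' length (amino-acid composition, AAC); with `normalize = FALSE` raw counts
#' are returned (occurrence). Non-standard letters are dropped before
#' counting.
#'
#' @param sequence Amino-acid string.
#' @param normalize Divide counts by effective length?
#' @return Named numeric vector of length 20.
#' @export
composition <- function(sequence, normalize = TRUE) {
  letters <- strsplit(toupper(sequence), "")[[1]]
  letters <- letters[letters %in% aa_order()]
  if (length(letters) == 0L) {
    abort_input("sequence contains no standard amino acids")
  }
  counts <- table(factor(letters, levels = aa_order()))
  out <- as.numeric(counts)
  names(out) <- aa_order()
  if (normalize) out / length(letters) else out
}

#' Ordered pair frequencies over the raw sequence (PF1 / PF2)
#'
#' Counts ordered residue pairs: `gap = 0` pairs adjacent residues
#' (positions i, i+1; the 400-dimensional PF2 set) and `gap = 1` pairs
#' residues separated by one intervening residue (positions i, i+2; PF1).
#' Pairs involving non-standard letters are skipped. The 400 counts are laid
#' out row-major in canonical order (first residue varies slowest).
#'
#' @param sequence Amino-acid string.
#' @param gap Number of intervening residues, 0 or 1.
#' @return Named numeric vector of length 400.
#' @export
sequence_pair_features <- function(sequence, gap = 0L) {
  if (!gap %in% c(0L, 1L)) abort_input("gap must be 0 or 1")
  letters <- strsplit(toupper(sequence), "")[[1]]
  L <- length(letters)
  step <- gap + 1L
  if (L < step + 1L) {
    abort_input("sequence of length %d is too short for pairs with gap %d", L, gap)
  }
  first <- factor(letters[seq_len(L - step)], levels = aa_order())
  second <- factor(letters[seq_len(L - step) + step], levels = aa_order())
  counts <- table(first, second)
  out <- as.vector(t(counts))  # row-major over (first, second)
  names(out) <- pair_feature_names(paste0("g", gap))
  out
}

#' Concatenated pair-frequency features (PF)
#'
#' PF1 (one intervening residue) followed by PF2 (adjacent), 800 features.
#'
#' @param sequence Amino-acid string.
#' @return Named numeric vector of length 800.
#' @export
sequence_pf <- function(sequence) {
  c(sequence_pair_features(sequence, gap = 1L),
    sequence_pair_features(sequence, gap = 0L))
}

#' Profile-based mono-gram and bi-gram features
#'
#' Profile analogues of residue composition and adjacent-pair composition,
#' computed from the PSSM probability block alone. Order 1 returns the 20
#' column sums of P; order 2 returns the 400-entry matrix
#' `B(m, n) = sum_{i=1}^{L-1} P[i, m] * P[i+1, n]`, i.e. the k = 1 pair
#' product restricted to the evolutionary block, flattened row-major.
#'
#' @param profile A [protein_profile()].
#' @param order 1 (mono-gram) or 2 (bi-gram).
#' @param normalize Divide mono-gram column sums by L? Off by default.
#' @return Named numeric vector of length 20 (order 1) or 400 (order 2).
#' @export
pssm_ngram <- function(profile, order = 1L, normalize = FALSE) {
  if (!order %in% c(1L, 2L)) abort_input("order must be 1 or 2")
  L <- nrow(profile$P)
  if (L < order) abort_input("profile of length %d too short for order %d", L, order)
  if (order == 1L) {
    out <- colSums(profile$P)
    if (normalize) out <- out / L
    names(out) <- aa_order()
    return(out)
  }
  out <- kaap_single(profile$P, k = 1L)$flat
  names(out) <- pair_feature_names("bg")
  out
}

# ---- extractor registry ----------------------------------------------------

# Each extractor declares its dimensionality (at default settings) and which
# input it consumes; extract_features() dispatches through this table.
extractor_table <- function(k_max = 4L, ss_states = 3L) {
  m <- 20L + ss_states
  list(
    kaap       = list(dim = as.integer(k_max * m^2), input = "profile",
                      fn = function(p, ...) kaap_full(build_Q(p), k_max = k_max)),
    monogram   = list(dim = 20L, input = "profile",
                      fn = function(p, ...) pssm_ngram(p, order = 1L, ...)),
    bigram     = list(dim = 400L, input = "profile",
                      fn = function(p, ...) pssm_ngram(p, order = 2L)),
    aac        = list(dim = 20L, input = "sequence",
                      fn = function(s, ...) composition(s, normalize = TRUE)),
    occurrence = list(dim = 20L, input = "sequence",
                      fn = function(s, ...) composition(s, normalize = FALSE)),
    pf1        = list(dim = 400L, input = "sequence",
                      fn = function(s, ...) sequence_pair_features(s, gap = 1L)),
    pf2        = list(dim = 400L, input = "sequence",
                      fn = function(s, ...) sequence_pair_features(s, gap = 0L)),
    pf         = list(dim = 800L, input = "sequence",
                      fn = function(s, ...) sequence_pf(s))
  )
}

#' Registered feature extractors
#'
#' @param k_max k-AAP separation bound used to report the k-AAP dimensionality.
#' @return A tibble with the extractor names, their dimensionality at default
#'   settings, and the input they consume (`"profile"` or `"sequence"`).
#' @export
list_extractors <- function(k_max = 4L) {
  reg <- extractor_table(k_max = k_max)
  tibble::tibble(
    extractor = names(reg),
    dimension = unname(vapply(reg, `[[`, integer(1), "dim")),
    input = unname(vapply(reg, `[[`, character(1), "input"))
  )
}

#' Extract a feature table from a set of profiles
#'
#' Applies a registered extractor to every profile and returns a tidy table:
#' one row per protein, with `protein_id`, `label`, and one numeric column per
#' feature. Sequence-based extractors can work from either the observed
#' sequence or the PSSM consensus sequence (the paper-style "PSSM + FET"
#' variants).
#'
#' @param profiles A list of [protein_profile()] objects.
#' @param extractor One of [list_extractors()]`$extractor`.
#' @param k_max k-AAP separation bound (used by `extractor = "kaap"`).
#' @param use_consensus For sequence-based extractors, replace each sequence
#'   by its PSSM consensus before extraction.
#' @param ... Passed to the extractor (e.g. `normalize` for `monogram`).
#' @return A tibble of `length(profiles)` rows. Attributes `extractor` and
#'   `k_max` record what produced it.
#' @export
extract_features <- function(profiles, extractor = "kaap", k_max = 4L,
                             use_consensus = FALSE, ...) {
  if (inherits(profiles, "protein_profile")) profiles <- list(profiles)
  reg <- extractor_table(k_max = k_max)
  if (!extractor %in% names(reg)) {
    abort_input("unknown extractor '%s'; see list_extractors()", extractor)
  }
  entry <- reg[[extractor]]
  rows <- purrr::map(profiles, function(p) {
    if (entry$input == "profile") {
      entry$fn(p, ...)
    } else {
      entry$fn(if (use_consensus) consensus_sequence(p) else p$sequence, ...)
    }
  })
  mat <- do.call(rbind, rows)
  if (is.null(colnames(mat))) {
    colnames(mat) <- paste0("f", seq_len(ncol(mat)))
  }
  out <- tibble::tibble(
    protein_id = purrr::map_chr(profiles, "protein_id"),
    label = purrr::map_chr(profiles, function(p) {
      if (is.null(p$label)) NA_character_ else as.character(p$label)
    })
  )
  out <- dplyr::bind_cols(out, tibble::as_tibble(mat))
  attr(out, "extractor") <- extractor
  attr(out, "k_max") <- if (extractor == "kaap") k_max else NA_integer_
  out
}

# Numeric feature matrix from a feature tibble (drops id/label columns).
feature_matrix <- function(features) {
  as.matrix(dplyr::select(features, -dplyr::any_of(c("protein_id", "label"))))
}
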