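# Readers for the external file formats (PSI-BLAST ASCII PSSM, SPINE-X
# secondary-structure predictions, FASTA, label manifests) and assembly of
# per-protein profiles.

#' Read a PSI-BLAST ASCII PSSM file
#'
#' Parses the `-out_ascii_pssm` dialect: a header line listing the 20
#' amino-acid columns twice (log-odds block, then weighted observed
#' percentages), followed by one row per residue with the residue index, the
#' residue letter, 20 integer log-odds scores and 20 integer percentages.
#' Trailing per-row statistics (information content, relative weight) and the
#' K/lambda footer are ignored. Columns are re-ordered into the canonical
#' amino-acid order [aa_order()] regardless of the order in the file header.
#'
#' @param path Path to an ASCII PSSM file.
#' @return An object of class `raw_pssm`: a list with `protein_id` (file stem),
#'   `residues` (character vector, length L), `log_odds` and `percentages`
#'   (integer L x 20 matrices, canonical column order), and `column_order`
#'   (the canonical order the matrices are stored in).
#' @seealso [read_sspm()], [assemble_profile()]
#' @export
read_pssm <- function(path) {
  if (!file.exists(path)) abort_input("PSSM file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(is_content_line(lines))

  aa <- aa_order()
  header_idx <- NA_integer_
  header_letters <- NULL
  for (i in keep) {
    fields <- split_fields(lines[i])
    letters <- fields[fields %in% aa & nchar(fields) == 1L]
    if (length(letters) >= 40L) {
      header_idx <- i
      header_letters <- letters
      break
    }
  }
  if (is.na(header_idx)) {
    abort_format("no PSSM header line listing the 20 amino-acid columns twice found in %s", path)
  }
  lo_order <- header_letters[1:20]
  pc_order <- header_letters[21:40]
  if (!setequal(lo_order, aa) || !setequal(pc_order, aa)) {
    abort_format("malformed PSSM header at line %d of %s: columns are not the 20 standard amino acids",
                 header_idx, path)
  }

  residues <- character(0)
  log_odds <- list()
  percentages <- list()
  row_i <- 0L
  for (i in keep[keep > header_idx]) {
    fields <- split_fields(lines[i])
    # Data rows start with a residue index and a residue letter; the first
    # line that does not (the K/lambda footer) ends the block.
    idx <- parse_num(fields[1])
    if (length(fields) < 2L || is.na(idx) || !grepl("^[A-Za-z*]$", fields[2])) break
    row_i <- row_i + 1L
    vals <- parse_num(fields[-(1:2)])
    vals <- vals[!is.na(vals)]
    if (length(vals) < 40L) {
      abort_format("PSSM row %d of %s has %d numeric fields; expected the 40 score columns",
                   row_i, path, length(vals))
    }
    residues[row_i] <- toupper(fields[2])
    log_odds[[row_i]] <- vals[1:20]
    percentages[[row_i]] <- vals[21:40]
  }
  if (row_i == 0L) abort_format("PSSM file %s contains no residue rows", path)

  lo <- do.call(rbind, log_odds)
  pc <- do.call(rbind, percentages)
  # Canonicalize column order per block using its own header segment.
  lo <- lo[, match(aa, lo_order), drop = FALSE]
  pc <- pc[, match(aa, pc_order), drop = FALSE]
  colnames(lo) <- aa
  colnames(pc) <- aa
  if (any(pc < 0 | pc > 100)) {
    abort_format("PSSM file %s has percentage entries outside [0, 100]", path)
  }

  structure(
    list(
      protein_id = tools::file_path_sans_ext(basename(path)),
      residues = residues,
      log_odds = lo,
      percentages = pc,
      column_order = aa
    ),
    class = "raw_pssm"
  )
}

#' Read a SPINE-X-style secondary-structure prediction file
#'
#' Parses a whitespace-delimited per-residue prediction table carrying
#' helix/strand/coil probabilities. Column positions are explicit, never
#' auto-detected: by default the probabilities are taken from the last three
#' columns of each row in the order coil, helix, strand (the SPINE-X layout)
#' and stored internally in the order helix, strand, coil ([ss_order()]).
#' Rows whose probabilities sum to within `1e-3` of one are renormalized to
#' sum exactly one; larger deviations are format errors.
#'
#' @param path Path to the prediction file.
#' @param prob_cols Integer vector of three 1-based column indices holding the
#'   probabilities, or `NULL` (default) for the last three columns of each row.
#' @param prob_order Character vector naming the states carried by `prob_cols`,
#'   a permutation of `c("coil", "helix", "strand")` (the SPINE-X default).
#' @param residue_col 1-based column index of the residue letter, or `NULL`.
#' @return An object of class `raw_sspm`: a list with `protein_id`, `residues`
#'   (possibly `NA`), `probs` (L x 3 matrix, columns H, E, C, rows summing to
#'   one) and `predicted_state` (per-residue argmax letter).
#' @export
read_sspm <- function(path, prob_cols = NULL,
                      prob_order = c("coil", "helix", "strand"),
                      residue_col = 2L) {
  if (!file.exists(path)) abort_input("secondary-structure file not found: %s", path)
  if (!setequal(prob_order, c("coil", "helix", "strand"))) {
    abort_input("prob_order must be a permutation of coil, helix, strand")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[is_content_line(lines)]

  rows <- list()
  residues <- character(0)
  n <- 0L
  for (line in lines) {
    fields <- split_fields(line)
    cols <- if (is.null(prob_cols)) seq(length(fields) - 2L, length(fields)) else prob_cols
    if (min(cols) < 1L || max(cols) > length(fields)) next
    vals <- parse_num(fields[cols])
    if (anyNA(vals)) next  # header / annotation line
    n <- n + 1L
    if (any(vals < -1e-3 | vals > 1 + 1e-3)) {
      abort_format("probability outside [0, 1] at residue row %d of %s", n, path)
    }
    rows[[n]] <- pmin(pmax(vals, 0), 1)
    residues[n] <- if (!is.null(residue_col) && residue_col <= length(fields) &&
                       grepl("^[A-Za-z*]$", fields[residue_col])) {
      toupper(fields[residue_col])
    } else NA_character_
  }
  if (n == 0L) abort_format("no residue rows found in %s", path)

  probs <- do.call(rbind, rows)
  sums <- rowSums(probs)
  bad <- which(abs(sums - 1) > 1e-3)
  if (length(bad) > 0L) {
    abort_format("row %d of %s has probabilities summing to %.4f (must be within 1e-3 of 1)",
                 bad[1], path, sums[bad[1]])
  }
  probs <- probs / sums

  # File order (default coil, helix, strand) -> internal helix, strand, coil.
  internal <- c(helix = "H", strand = "E", coil = "C")[prob_order]
  probs <- probs[, match(ss_order(), internal), drop = FALSE]
  colnames(probs) <- ss_order()

  structure(
    list(
      protein_id = tools::file_path_sans_ext(basename(path)),
      residues = residues,
      probs = probs,
      predicted_state = ss_order()[max.col(probs, ties.method = "first")]
    ),
    class = "raw_sspm"
  )
}

#' Construct a protein profile
#'
#' A protein profile carries the per-residue evolutionary probabilities `P`
#' (L x 20, canonical amino-acid columns) and secondary-structure
#' probabilities `S` (L x 3, columns H, E, C), each row-stochastic, together
#' with the residue sequence and an optional fold label.
#'
#' @param protein_id Identifier string.
#' @param sequence Amino-acid string of length L.
#' @param P Numeric L x 20 matrix; rows are renormalized to sum to one
#'   (all-zero rows become uniform).
#' @param S Numeric L x 3 matrix; rows renormalized likewise.
#' @param label Optional fold label.
#' @return An object of class `protein_profile`.
#' @export
protein_profile <- function(protein_id, sequence, P, S, label = NULL) {
  P <- as.matrix(P)
  S <- as.matrix(S)
  L <- nchar(sequence)
  if (nrow(P) != L || nrow(S) != L) {
    abort_input("profile %s: sequence length %d does not match P (%d rows) and S (%d rows)",
                protein_id, L, nrow(P), nrow(S))
  }
  if (ncol(P) != 20L) abort_input("profile %s: P must have 20 columns", protein_id)
  P <- row_stochastic(P)
  S <- row_stochastic(S)
  colnames(P) <- aa_order()
  if (ncol(S) == 3L) colnames(S) <- ss_order()
  structure(
    list(protein_id = protein_id, sequence = sequence, P = P, S = S,
         label = label),
    class = "protein_profile"
  )
}

#' @export
print.protein_profile <- function(x, ...) {
  cat(sprintf("<protein_profile> %s: L = %d, label = %s\n",
              x$protein_id, nrow(x$P),
              if (is.null(x$label)) "<none>" else as.character(x$label)))
  invisible(x)
}

#' Assemble a protein profile from parsed PSSM and secondary-structure files
#'
#' Converts the PSSM to linear probabilities and pairs it with the
#' secondary-structure probabilities. Two conversion modes are supported:
#' `"percentage"` (default) divides the weighted-percentage block by 100 and
#' renormalizes each row (the block is already an empirical probability);
#' `"logistic"` applies `1 / (1 + exp(-score))` element-wise to the log-odds
#' block before row renormalization. All-zero rows become uniform in either
#' mode, keeping every row stochastic.
#'
#' @param raw_pssm A [read_pssm()] result.
#' @param raw_sspm A [read_sspm()] result for the same protein.
#' @param mode Probability conversion mode, `"percentage"` or `"logistic"`.
#' @param label Optional fold label attached to the profile.
#' @param min_agreement Minimum fraction of positions at which the residue
#'   letters of the two files must agree (ambiguous letters B, Z, X, U and
#'   missing letters are exempt).
#' @return A [protein_profile()].
#' @export
assemble_profile <- function(raw_pssm, raw_sspm,
                             mode = c("percentage", "logistic"),
                             label = NULL, min_agreement = 0.95) {
  mode <- match.arg(mode)
  L <- length(raw_pssm$residues)
  if (L != nrow(raw_sspm$probs)) {
    abort_input("cannot pair %s (L = %d) with %s (L = %d): lengths differ",
                raw_pssm$protein_id, L, raw_sspm$protein_id, nrow(raw_sspm$probs))
  }
  comparable <- !is.na(raw_sspm$residues) &
    !(raw_pssm$residues %in% c("B", "Z", "X", "U", "*")) &
    !(raw_sspm$residues %in% c("B", "Z", "X", "U", "*"))
  if (any(comparable)) {
    agree <- mean(raw_pssm$residues[comparable] == raw_sspm$residues[comparable])
    if (agree < min_agreement) {
      abort_input("residues of %s and %s agree at only %.0f%% of comparable positions",
                  raw_pssm$protein_id, raw_sspm$protein_id, 100 * agree)
    }
  }
  P <- switch(mode,
    percentage = raw_pssm$percentages / 100,
    logistic = 1 / (1 + exp(-raw_pssm$log_odds))
  )
  prof <- protein_profile(
    protein_id = raw_pssm$protein_id,
    sequence = paste(raw_pssm$residues, collapse = ""),
    P = P, S = raw_sspm$probs, label = label
  )
  attr(prof, "conversion_mode") <- mode
  prof
}

#' Read protein sequences from a FASTA file
#'
#' @param path Path to a FASTA file of amino-acid sequences.
#' @return A tibble with columns `protein_id` and `sequence`.
#' @export
read_fasta_sequences <- function(path) {
  seqs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             forceDNAtolower = FALSE)
  tibble::tibble(
    protein_id = names(seqs),
    sequence = unname(toupper(vapply(seqs, `[[`, character(1), 1)))
  )
}

#' Read a label manifest
#'
#' A manifest is a two-column whitespace- or tab-delimited text file mapping
#' protein identifiers to fold labels. Lines starting with `#` are ignored.
#'
#' @param path Path to the manifest file.
#' @return A tibble with columns `protein_id` and `label`.
#' @export
read_label_manifest <- function(path) {
  if (!file.exists(path)) abort_input("manifest not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[is_content_line(lines)]
  fields <- lapply(lines, split_fields)
  bad <- which(lengths(fields) < 2L)
  if (length(bad) > 0L) {
    abort_format("manifest line %d has fewer than two fields", bad[1])
  }
  out <- tibble::tibble(
    protein_id = vapply(fields, `[[`, character(1), 1),
    label = vapply(fields, `[[`, character(1), 2)
  )
  if (anyDuplicated(out$protein_id)) {
    abort_input("manifest contains duplicated protein ids (e.g. %s)",
                out$protein_id[anyDuplicated(out$protein_id)])
  }
  out
}

#' Load a directory tree of PSSM/SSPM files into profiles
#'
#' Reads the manifest, then for each protein reads `<id>.pssm` and `<id>.sspm`
#' from the given directories and assembles a labelled profile.
#'
#' @param manifest Path to the label manifest.
#' @param pssm_dir,sspm_dir Directories holding per-protein files.
#' @param mode Probability conversion mode passed to [assemble_profile()].
#' @param on_missing `"fail"` (default) or `"skip"` proteins whose files are
#'   missing (skips are reported via a warning).
#' @return A list of [protein_profile()] objects.
#' @export
read_profile_tree <- function(manifest, pssm_dir, sspm_dir,
                              mode = c("percentage", "logistic"),
                              on_missing = c("fail", "skip")) {
  mode <- match.arg(mode)
  on_missing <- match.arg(on_missing)
  man <- read_label_manifest(manifest)
  profiles <- list()
  skipped <- character(0)
  for (i in seq_len(nrow(man))) {
    id <- man$protein_id[i]
    pssm_path <- file.path(pssm_dir, paste0(id, ".pssm"))
    sspm_path <- file.path(sspm_dir, paste0(id, ".sspm"))
    if (!file.exists(pssm_path) || !file.exists(sspm_path)) {
      if (on_missing == "fail") {
        abort_input("missing profile files for %s (looked for %s and %s)",
                    id, pssm_path, sspm_path)
      }
      skipped <- c(skipped, id)
      next
    }
    profiles[[length(profiles) + 1L]] <- assemble_profile(
      read_pssm(pssm_path), read_sspm(sspm_path),
      mode = mode, label = man$label[i]
    )
  }
  if (length(skipped) > 0L) {
    warning(sprintf("skipped %d proteins with missing files: %s",
                    length(skipped), paste(utils::head(skipped, 5), collapse = ", ")))
  }
  profiles
}
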