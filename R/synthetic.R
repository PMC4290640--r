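# Seeded generator of fold-structured synthetic datasets: latent residue
# sequences with class-specific composition and lag-correlated pair motifs,
# evolutionary probability rows as temperature-smoothed one-hots around the
# latent residues, and secondary-structure rows from a persistent two-state
# Markov segment model. Also writes fixture trees in the exact file dialects
# the readers parse.

#' Specification of a synthetic fold-structured dataset
#'
#' Describes the generative model for one dataset. Each class has a Dirichlet
#' concentration vector over the 20 amino acids (its residue emission), a
#' Dirichlet concentration over the helix/strand/coil states, and a set of
#' pair-correlation motif rules `(lag, source, target, strength)`: at a
#' fraction `strength` of evenly spaced candidate slots, the latent residue at
#' the slot is set to `source` and the residue `lag` positions downstream to
#' `target`. Slots are spaced `lag + 5` apart so motif instances never create
#' cross-instance pair correlations at separations up to 4. Classes whose
#' emission (or state) concentration rows are identical share a single drawn
#' probability vector, so "identical emissions" holds exactly.
#'
#' The observed sequence is the latent sequence with each position mutated to
#' a uniformly random amino acid with probability `seq_mutation_rate`; the
#' evolutionary probability rows stay centred on the latent residue. This
#' mirrors real data, where a profile averaged over homologs is less noisy
#' than any single sequence.
#'
#' @param n_classes Number of fold classes (>= 2).
#' @param proteins_per_class Proteins generated per class.
#' @param length_range Integer `c(min, max)` residue lengths.
#' @param emission `n_classes` x 20 matrix of Dirichlet concentrations (rows
#'   may repeat to share emissions). Default: uniform concentration 2.
#' @param motifs Data frame with columns `class` (1-based class index), `lag`,
#'   `source`, `target` (single letters), `strength` in \[0, 1\]. May be empty.
#' @param ss_bias `n_classes` x 3 matrix of Dirichlet concentrations over
#'   (helix, strand, coil).
#' @param noise_temperature Mixing weight in \[0, 1) of Dirichlet noise added
#'   to the one-hot probability rows; 0 gives exact one-hots.
#' @param seq_mutation_rate Per-position probability that the observed
#'   sequence letter is replaced by a uniform random amino acid.
#' @param ss_mean_segment Mean secondary-structure segment length (geometric).
#' @param seed Integer seed; the dataset is a pure function of the spec.
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(n_classes = 4L, proteins_per_class = 60L,
                       length_range = c(50L, 120L),
                       emission = NULL, motifs = NULL, ss_bias = NULL,
                       noise_temperature = 0.15, seq_mutation_rate = 0.3,
                       ss_mean_segment = 6, seed = 7L) {
  if (n_classes < 2L) abort_input("n_classes must be at least 2")
  if (is.null(emission)) {
    emission <- matrix(2, n_classes, 20, dimnames = list(NULL, aa_order()))
  }
  if (is.null(ss_bias)) {
    ss_bias <- matrix(3, n_classes, 3, dimnames = list(NULL, ss_order()))
  }
  if (is.null(motifs)) {
    motifs <- data.frame(class = integer(0), lag = integer(0),
                         source = character(0), target = character(0),
                         strength = numeric(0))
  }
  if (nrow(motifs) > 0L) {
    if (any(motifs$lag < 1L)) abort_input("motif lags must be >= 1")
    if (any(motifs$lag >= length_range[1])) {
      abort_input("motif lag %d is not below the minimum length %d",
                  max(motifs$lag), length_range[1])
    }
    if (any(motifs$strength < 0)) abort_input("motif strengths must be >= 0")
    if (!all(motifs$source %in% aa_order() & motifs$target %in% aa_order())) {
      abort_input("motif source/target must be standard amino-acid letters")
    }
  }
  if (noise_temperature < 0 || noise_temperature >= 1) {
    abort_input("noise_temperature must be in [0, 1)")
  }
  structure(
    list(n_classes = as.integer(n_classes),
         proteins_per_class = as.integer(proteins_per_class),
         length_range = as.integer(length_range),
         emission = emission, motifs = motifs, ss_bias = ss_bias,
         noise_temperature = noise_temperature,
         seq_mutation_rate = seq_mutation_rate,
         ss_mean_segment = ss_mean_segment,
         seed = as.integer(seed)),
    class = "synth_spec"
  )
}

#' Preset: an easily separable 4-class dataset
#'
#' Four classes of 60 proteins (lengths 50-120) that differ in residue
#' composition, in strong pair motifs at separations 1-4, and in
#' secondary-structure state bias (helix-rich, strand-rich, mixed,
#' coil-rich) — every signal channel the pair features can exploit.
#'
#' @param seed Integer seed.
#' @param proteins_per_class Override the per-class count.
#' @return A [synth_spec()].
#' @export
easy_spec <- function(seed = 7L, proteins_per_class = 60L) {
  emission <- matrix(1, 4, 20, dimnames = list(NULL, aa_order()))
  favored <- list(c("A", "E", "L"), c("G", "K", "V"), c("D", "F", "S"), c("I", "R", "T"))
  for (c in 1:4) emission[c, favored[[c]]] <- 7
  motifs <- data.frame(
    class = rep(1:4, each = 2),
    lag = c(1L, 3L, 1L, 3L, 2L, 4L, 2L, 4L),
    source = c("A", "L", "E", "K", "G", "S", "F", "T"),
    target = c("E", "K", "A", "L", "F", "T", "G", "S"),
    strength = 0.9
  )
  ss_bias <- rbind(c(8, 1, 3), c(1, 8, 3), c(4, 4, 4), c(2, 2, 8))
  colnames(ss_bias) <- ss_order()
  synth_spec(n_classes = 4L, proteins_per_class = proteins_per_class,
             length_range = c(50L, 120L), emission = emission,
             motifs = motifs, ss_bias = ss_bias,
             noise_temperature = 0.15, seq_mutation_rate = 0.3, seed = seed)
}

#' Preset: lag-graded signal for comparing feature families
#'
#' Four classes whose separability is layered so that no single channel
#' saturates. The background emission is shared exactly by all classes;
#' class signal enters only through the motif letters. Classes come in
#' reversed-motif pairs (class 2 implants the letter-reversed pairs of
#' class 1), so single-residue composition can tell the pairs apart but
#' never the classes within a pair; the adjacent-pair direction separates
#' classes within a pair from profile bi-grams up; and the separation-3
#' pair direction plus a class-specific secondary-structure bias is visible
#' only to the full pair features over the concatenated profile. A heavy
#' mutation rate further dilutes the observed sequence relative to the
#' profile, grading raw-sequence composition below profile composition.
#'
#' @param seed Integer seed.
#' @param proteins_per_class Override the per-class count.
#' @return A [synth_spec()].
#' @export
ordering_spec <- function(seed = 7L, proteins_per_class = 40L) {
  emission <- matrix(2, 4, 20, dimnames = list(NULL, aa_order()))
  motifs <- data.frame(
    class = rep(1:4, each = 2),
    lag = rep(c(1L, 3L), 4),
    source = c("A", "L",  "E", "K",  "G", "S",  "F", "T"),
    target = c("E", "K",  "A", "L",  "F", "T",  "G", "S"),
    strength = rep(c(0.3, 0.75), 4)
  )
  ss_bias <- rbind(c(6, 1, 3), c(1, 6, 3), c(3, 3, 3), c(2, 2, 6))
  colnames(ss_bias) <- ss_order()
  synth_spec(n_classes = 4L, proteins_per_class = proteins_per_class,
             length_range = c(60L, 100L), emission = emission,
             motifs = motifs, ss_bias = ss_bias,
             noise_temperature = 0.25, seq_mutation_rate = 0.6, seed = seed)
}

#' Preset: two classes distinguished only by a reciprocal lag-3 pair rule
#'
#' Emissions and secondary-structure biases are shared exactly between the
#' classes; class 1 implants C -> W pairs at separation 3, class 2 the
#' reversed W -> C pairs at the same rate, so single-residue composition is
#' class-independent by construction and all signal lives in the ordered
#' pair structure at separation 3.
#'
#' @param seed Integer seed.
#' @param proteins_per_class Proteins per class.
#' @return A [synth_spec()].
#' @export
lag_only_spec <- function(seed = 7L, proteins_per_class = 40L) {
  motifs <- data.frame(
    class = 1:2, lag = 3L,
    source = c("C", "W"), target = c("W", "C"),
    strength = 0.8
  )
  synth_spec(n_classes = 2L, proteins_per_class = proteins_per_class,
             length_range = c(60L, 100L),
             emission = matrix(2, 2, 20, dimnames = list(NULL, aa_order())),
             motifs = motifs,
             ss_bias = matrix(3, 2, 3, dimnames = list(NULL, ss_order())),
             noise_temperature = 0.05, seq_mutation_rate = 0, seed = seed)
}

# One Dirichlet draw.
rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha)
  if (sum(g) <= 0) g <- rep(1, length(alpha))
  g / sum(g)
}

# Draw one probability vector per concentration row, sharing draws between
# identical rows so identical concentrations mean identical distributions.
draw_class_probs <- function(conc) {
  keys <- apply(conc, 1, paste, collapse = ",")
  drawn <- list()
  t(vapply(keys, function(k) {
    if (is.null(drawn[[k]])) drawn[[k]] <<- rdirichlet1(conc[match(k, keys), ])
    drawn[[k]]
  }, numeric(ncol(conc))))
}

#' Generate a synthetic fold-structured dataset
#'
#' Realizes a [synth_spec()]: samples per-protein lengths, latent residue
#' sequences from the class emission, implants the class pair motifs,
#' produces the evolutionary probability block as noise-smoothed one-hot rows
#' around the latent residues, the structural block from a persistent Markov
#' chain over helix/strand/coil, and the observed sequence as a mutated copy
#' of the latent one. The result is a pure function of the spec (including
#' its seed).
#'
#' @param spec A [synth_spec()].
#' @return An object of class `kaap_synth`: list with `profiles` (list of
#'   [protein_profile()]), `manifest` (tibble `protein_id`, `label`),
#'   `latent` (character vector of latent sequences) and `spec`.
#' @export
generate_profiles <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  withr::with_seed(spec$seed, {
    emission <- draw_class_probs(spec$emission)
    ss_probs <- draw_class_probs(spec$ss_bias)
    stay <- 1 - 1 / spec$ss_mean_segment
    tau <- spec$noise_temperature

    profiles <- list()
    latent_seqs <- character(0)
    for (cls in seq_len(spec$n_classes)) {
      rules <- spec$motifs[spec$motifs$class == cls, , drop = FALSE]
      for (j in seq_len(spec$proteins_per_class)) {
        L <- sample(seq(spec$length_range[1], spec$length_range[2]), 1)
        latent <- sample(aa_order(), L, replace = TRUE, prob = emission[cls, ])

        # implant pair motifs on slot grids spaced lag + 5 apart
        for (r in seq_len(nrow(rules))) {
          lag <- rules$lag[r]
          step <- lag + 5L
          offset <- sample.int(step, 1)
          starts <- seq(offset, L - lag, by = step)
          if (length(starts) == 0L) next
          use <- starts[stats::runif(length(starts)) < rules$strength[r]]
          latent[use] <- rules$source[r]
          latent[use + lag] <- rules$target[r]
        }

        # evolutionary block: noise-smoothed one-hot on the latent residue
        P <- matrix(0, L, 20, dimnames = list(NULL, aa_order()))
        P[cbind(seq_len(L), match(latent, aa_order()))] <- 1
        if (tau > 0) {
          noise <- matrix(stats::rgamma(L * 20, shape = 1), L, 20)
          P <- (1 - tau) * P + tau * noise / rowSums(noise)
        }

        # structural block: persistent Markov chain over H/E/C
        states <- integer(L)
        states[1] <- sample.int(3, 1, prob = ss_probs[cls, ])
        if (L > 1) for (i in 2:L) {
          states[i] <- if (stats::runif(1) < stay) states[i - 1] else
            sample.int(3, 1, prob = ss_probs[cls, ])
        }
        S <- matrix(0, L, 3, dimnames = list(NULL, ss_order()))
        S[cbind(seq_len(L), states)] <- 1
        if (tau > 0) {
          noise <- matrix(stats::rgamma(L * 3, shape = 1), L, 3)
          S <- (1 - tau) * S + tau * noise / rowSums(noise)
        }

        # observed sequence: mutated copy of the latent sequence
        observed <- latent
        if (spec$seq_mutation_rate > 0) {
          hit <- stats::runif(L) < spec$seq_mutation_rate
          observed[hit] <- sample(aa_order(), sum(hit), replace = TRUE)
        }

        id <- sprintf("C%02d_P%03d", cls, j)
        profiles[[length(profiles) + 1L]] <- protein_profile(
          protein_id = id, sequence = paste(observed, collapse = ""),
          P = P, S = S, label = paste0("fold", cls)
        )
        latent_seqs[id] <- paste(latent, collapse = "")
      }
    }
    structure(
      list(
        profiles = profiles,
        manifest = tibble::tibble(
          protein_id = vapply(profiles, `[[`, character(1), "protein_id"),
          label = vapply(profiles, `[[`, character(1), "label")
        ),
        latent = latent_seqs,
        spec = spec
      ),
      class = "kaap_synth"
    )
  })
}

#' @export
print.kaap_synth <- function(x, ...) {
  cat(sprintf("<kaap_synth> %d proteins, %d classes, seed %d\n",
              length(x$profiles), x$spec$n_classes, x$spec$seed))
  invisible(x)
}

#' Feature indices carrying the implanted motif signal
#'
#' Maps each motif rule of a spec to the position of its `(k, source, target)`
#' entry in the full pair-feature vector (separations 1..`k_max`, row-major
#' flattening), e.g. to ablate exactly the features the generator loaded with
#' class signal.
#'
#' @param spec A [synth_spec()].
#' @param k_max Separation bound the feature vector was built with.
#' @return Sorted unique integer indices into the `k_max * 529` vector.
#' @export
motif_feature_indices <- function(spec, k_max = 4L) {
  cols <- q_colnames()
  m <- length(cols)
  rules <- spec$motifs[spec$motifs$lag <= k_max, , drop = FALSE]
  if (nrow(rules) == 0L) return(integer(0))
  idx <- (rules$lag - 1L) * m^2 +
    (match(rules$source, cols) - 1L) * m +
    match(rules$target, cols)
  sort(unique(idx))
}

# Largest-remainder rounding of a probability row to integer percentages
# summing to 100.
quantize_percent <- function(p) {
  v <- 100 * p / sum(p)
  fl <- floor(v)
  short <- 100L - as.integer(sum(fl))
  if (short > 0L) {
    extra <- order(v - fl, decreasing = TRUE)[seq_len(short)]
    fl[extra] <- fl[extra] + 1
  }
  as.integer(fl)
}

#' Write one profile as a PSI-BLAST-style ASCII PSSM file
#'
#' Emits the `-out_ascii_pssm` dialect: the two-block header, one row per
#' residue with 20 integer log-odds scores (derived from the probabilities
#' against a uniform background) and 20 integer percentages (largest-remainder
#' rounding of the probability row, summing to 100), per-row information
#' content, and the K/lambda footer.
#'
#' @param profile A [protein_profile()].
#' @param path Output path.
#' @export
write_pssm_file <- function(profile, path) {
  aa <- aa_order()
  L <- nrow(profile$P)
  lines <- c(
    "",
    "Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts",
    paste0(strrep(" ", 11), paste(sprintf("%3s", c(aa, aa)), collapse = ""))
  )
  letters_seq <- strsplit(profile$sequence, "")[[1]]
  for (i in seq_len(L)) {
    p <- profile$P[i, ]
    pct <- quantize_percent(p)
    lo <- pmin(pmax(round(2 * log2(pmax(p, 1e-4) / 0.05)), -12), 13)
    info <- max(0, log2(20) + sum(ifelse(p > 0, p * log2(p), 0)))
    lines <- c(lines, paste0(
      sprintf("%5d %s  ", i, letters_seq[i]),
      paste(sprintf("%4d", lo), collapse = ""),
      paste(sprintf("%4d", pct), collapse = ""),
      sprintf("  %5.2f %8.2f", info, 1)
    ))
  }
  lines <- c(lines, "", "                      K         Lambda",
             "Standard Ungapped    0.1347     0.3179")
  writeLines(lines, path)
}

#' Write one profile as a SPINE-X-style secondary-structure file
#'
#' One row per residue: index, residue letter, predicted state, then the
#' probabilities in file order coil, helix, strand (the layout [read_sspm()]
#' expects by default).
#'
#' @param profile A [protein_profile()].
#' @param path Output path.
#' @export
write_sspm_file <- function(profile, path) {
  letters_seq <- strsplit(profile$sequence, "")[[1]]
  state <- ss_order()[max.col(profile$S, ties.method = "first")]
  lines <- c(
    "# index AA SS P(C) P(H) P(E)",
    sprintf("%5d %s %s %12.10f %12.10f %12.10f",
            seq_len(nrow(profile$S)), letters_seq, state,
            profile$S[, "C"], profile$S[, "H"], profile$S[, "E"])
  )
  writeLines(lines, path)
}

#' Write a synthetic dataset as a fixture tree of profile files
#'
#' Creates `pssm/<id>.pssm` and `sspm/<id>.sspm` per protein plus
#' `manifest.tsv` under `root`, in the dialects the readers parse, so the
#' tree can be read back with [read_profile_tree()]. Evolutionary
#' probabilities are quantized to integer percentages; the round trip is
#' exact to within that quantization.
#'
#' @param dataset A [generate_profiles()] result.
#' @param root Output directory (created if needed).
#' @return `root`, invisibly.
#' @export
write_fixture_tree <- function(dataset, root) {
  stopifnot(inherits(dataset, "kaap_synth"))
  pssm_dir <- file.path(root, "pssm")
  sspm_dir <- file.path(root, "sspm")
  dir.create(pssm_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(sspm_dir, recursive = TRUE, showWarnings = FALSE)
  for (p in dataset$profiles) {
    write_pssm_file(p, file.path(pssm_dir, paste0(p$protein_id, ".pssm")))
    write_sspm_file(p, file.path(sspm_dir, paste0(p$protein_id, ".sspm")))
  }
  readr::write_tsv(dataset$manifest, file.path(root, "manifest.tsv"),
                   col_names = FALSE)
  invisible(root)
}
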