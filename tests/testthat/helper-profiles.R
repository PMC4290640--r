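# Fixture builders and independent oracles used across the suite.

# Random row-stochastic profile, independent of the package generator.
rand_profile <- function(L, id = "p1", label = NULL) {
  P <- matrix(stats::runif(L * 20), L, 20)
  S <- matrix(stats::runif(L * 3), L, 3)
  protein_profile(id, paste(sample(aa_order(), L, replace = TRUE), collapse = ""),
                  P = P, S = S, label = label)
}

# Independent brute-force pair accumulation: explicit loops over m, n, i.
oracle_pair_matrix <- function(Q, k) {
  L <- nrow(Q)
  m_tot <- ncol(Q)
  R <- matrix(0, m_tot, m_tot)
  for (m in seq_len(m_tot)) {
    for (n in seq_len(m_tot)) {
      acc <- 0
      i <- 1
      while (i + k <= L) {
        acc <- acc + Q[i, m] * Q[i + k, n]
        i <- i + 1
      }
      R[m, n] <- acc
    }
  }
  R
}

# Row-major flattening by explicit loops.
oracle_flatten <- function(R) {
  out <- numeric(0)
  for (m in seq_len(nrow(R))) out <- c(out, R[m, ])
  out
}

# Independent per-class confusion tally over every (item, class) pair.
oracle_confusion <- function(truth, predicted, classes) {
  res <- list()
  for (cl in classes) {
    tp <- fn <- fp <- tn <- 0L
    for (i in seq_along(truth)) {
      if (truth[i] == cl && predicted[i] == cl) tp <- tp + 1L
      else if (truth[i] == cl) fn <- fn + 1L
      else if (predicted[i] == cl) fp <- fp + 1L
      else tn <- tn + 1L
    }
    res[[cl]] <- c(TP = tp, FN = fn, TN = tn, FP = fp)
  }
  res
}

# Temporary file helper.
tmpfile <- function(ext = "") withr::local_tempfile(fileext = ext, .local_envir = parent.frame())

# A tiny hand-written, well-formed ASCII PSSM (3 residues) with the two
# 20-column blocks and footer, in canonical header order.
write_tiny_pssm <- function(path, perm = seq_len(20)) {
  aa <- aa_order()[perm]
  lo <- matrix(0L, 3, 20)
  pc <- matrix(0L, 3, 20)
  pc[1, ] <- c(100L, rep(0L, 19))     # in permuted file order
  pc[2, ] <- rep(5L, 20)
  pc[3, ] <- c(rep(0L, 19), 100L)
  lo[1, ] <- seq(-9L, 10L)
  lines <- c(
    "Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts",
    paste0(strrep(" ", 11), paste(sprintf("%4s", c(aa, aa)), collapse = ""))
  )
  res <- c("A", "R", "V")
  for (i in 1:3) {
    lines <- c(lines, paste0(
      sprintf("%5d %s  ", i, res[i]),
      paste(sprintf("%4d", lo[i, ]), collapse = ""),
      paste(sprintf("%4d", pc[i, ]), collapse = ""),
      "  0.36     0.12"
    ))
  }
  lines <- c(lines, "", "                      K         Lambda",
             "Standard Ungapped    0.1347     0.3179")
  writeLines(lines, path)
  list(log_odds = lo, percentages = pc, order = aa)
}
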