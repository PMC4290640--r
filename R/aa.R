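# Canonical orderings shared by every matrix in the package.

#' Canonical amino-acid column order
#'
#' The 20 standard amino acids in the order used by the PSI-BLAST ASCII PSSM
#' header (A, R, N, D, ...). Every 20-column matrix in the package uses this
#' order; parsers re-order file columns to it.
#'
#' @return Character vector of length 20.
#' @export
#' @examples
#' aa_order()
aa_order <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
}

#' Secondary-structure state order
#'
#' Internal column order of every secondary-structure probability block:
#' helix (H), strand (E), coil (C).
#'
#' @return Character vector of length 3.
#' @export
ss_order <- function() c("H", "E", "C")

# Column labels of Q = [P | S]: 20 amino acids then the s structure states,
# prefixed so H/E/C do not collide with the amino acids of the same letter.
q_colnames <- function(ss_states = ss_order()) {
  c(aa_order(), paste0("ss", ss_states))
}

# Names for the flattened pair-feature vector at shift k, row-major in (m, n).
kaap_feature_names <- function(k, ss_states = ss_order()) {
  cols <- q_colnames(ss_states)
  grid <- expand.grid(n = cols, m = cols, stringsAsFactors = FALSE)
  paste0("k", k, "_", grid$m, "_", grid$n)
}

pair_feature_names <- function(prefix) {
  grid <- expand.grid(n = aa_order(), m = aa_order(), stringsAsFactors = FALSE)
  paste0(prefix, "_", grid$m, "_", grid$n)
}
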