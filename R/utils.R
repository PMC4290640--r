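# Shared internal helpers.

abort_format <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "kaapfold_format_error")
}

abort_input <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "kaapfold_input_error")
}

# Split a line on runs of whitespace, dropping empty fields.
split_fields <- function(line) {
  fields <- strsplit(trimws(line), "[ \t]+")[[1]]
  fields[nzchar(fields)]
}

# Lines that carry data: not blank, not comments.
is_content_line <- function(lines) {
  stripped <- trimws(lines)
  nzchar(stripped) & !startsWith(stripped, "#")
}

# Locale-independent numeric parse: NA for non-numeric fields.
parse_num <- function(x) suppressWarnings(as.numeric(x))

# Renormalize matrix rows to sum to one; all-zero rows become uniform.
row_stochastic <- function(m) {
  sums <- rowSums(m)
  zero <- sums <= 0
  if (any(zero)) {
    m[zero, ] <- 1 / ncol(m)
    sums[zero] <- 1
  }
  m / sums
}
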