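# Feature-table serialization: dense delimited text and the sparse
# index:value convention of common SVM tools.

#' Write a feature table to disk
#'
#' Dense format: a delimited header plus one row per protein
#' (`protein_id`, `label`, then the feature values, full double precision).
#' Sparse format: one line per protein in the libsvm convention
#' `<label> <index>:<value> ...` with 1-based feature indices, zero entries
#' omitted, and the protein id in a trailing `# <id>` comment.
#'
#' @param features Feature tibble from [extract_features()] (columns
#'   `protein_id`, `label`, then features).
#' @param path Output path.
#' @param format `"dense"` or `"sparse"`.
#' @param delim Field delimiter for the dense format.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path, format = c("dense", "sparse"),
                                delim = ",") {
  format <- match.arg(format)
  if (!all(c("protein_id", "label") %in% names(features))) {
    abort_input("features must carry protein_id and label columns")
  }
  x <- feature_matrix(features)
  if (format == "dense") {
    readr::write_delim(features, path, delim = delim)
  } else {
    lines <- vapply(seq_len(nrow(x)), function(i) {
      nz <- which(x[i, ] != 0)
      paste0(features$label[i],
             if (length(nz) > 0)
               paste0(" ", paste0(nz, ":", sprintf("%.12g", x[i, nz]), collapse = " "))
             else "",
             " # ", features$protein_id[i])
    }, character(1))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path Input path.
#' @param format `"dense"` or `"sparse"`.
#' @param delim Field delimiter for the dense format.
#' @param n_features For the sparse format, the full vector length (columns
#'   beyond the largest stored index are zero); default is the largest index
#'   seen.
#' @return A feature tibble (`protein_id`, `label`, feature columns).
#' @export
read_feature_table <- function(path, format = c("dense", "sparse"),
                               delim = ",", n_features = NULL) {
  format <- match.arg(format)
  if (format == "dense") {
    out <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                             progress = FALSE)
    return(tibble::as_tibble(out))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parsed <- lapply(seq_along(lines), function(i) {
    line <- lines[i]
    id <- NA_character_
    if (grepl("#", line, fixed = TRUE)) {
      parts <- strsplit(line, "#", fixed = TRUE)[[1]]
      id <- trimws(parts[2])
      line <- parts[1]
    }
    fields <- split_fields(line)
    label <- fields[1]
    pairs <- fields[-1]
    if (length(pairs) > 0 && !all(grepl("^[0-9]+:", pairs))) {
      abort_format("sparse row %d has fields without index:value form", i)
    }
    idx <- as.integer(sub(":.*", "", pairs))
    val <- parse_num(sub("^[0-9]+:", "", pairs))
    list(id = if (is.na(id)) as.character(i) else id,
         label = label, idx = idx, val = val)
  })
  width <- if (is.null(n_features)) {
    max(c(0L, unlist(lapply(parsed, `[[`, "idx"))))
  } else n_features
  mat <- matrix(0, length(parsed), width)
  for (i in seq_along(parsed)) mat[i, parsed[[i]]$idx] <- parsed[[i]]$val
  colnames(mat) <- paste0("f", seq_len(width))
  dplyr::bind_cols(
    tibble::tibble(
      protein_id = vapply(parsed, `[[`, character(1), "id"),
      label = vapply(parsed, `[[`, character(1), "label")
    ),
    tibble::as_tibble(mat)
  )
}
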