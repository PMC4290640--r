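# Per-class one-vs-rest confusion counts and macro-averaged summary metrics.

#' Per-class confusion counts and rates
#'
#' Treats each class one-vs-rest and tallies true/false positives and
#' negatives over the test items, then derives per-class percentages:
#' sensitivity `100 * TP / (TP + FN)`, specificity `100 * TN / (TN + FP)`,
#' and precision `100 * TP / (TP + FP)`. Ratios with a zero denominator are
#' reported as 0 (with a warning), which occurs e.g. for precision when a
#' class is never predicted.
#'
#' @param truth Vector of true class labels.
#' @param predicted Vector of predicted labels, same length.
#' @param classes Classes to report; defaults to the union of observed labels.
#' @return A tibble with one row per class: `class`, `TP`, `FN`, `TN`, `FP`,
#'   `sensitivity`, `specificity`, `precision`.
#' @export
confusion_counts <- function(truth, predicted, classes = NULL) {
  if (length(truth) != length(predicted)) {
    abort_input("truth (%d) and predicted (%d) label vectors differ in length",
                length(truth), length(predicted))
  }
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  if (is.null(classes)) classes <- sort(unique(c(truth, predicted)))
  missing_cls <- setdiff(unique(truth), classes)
  if (length(missing_cls) > 0L) {
    abort_input("classes must cover all observed truth labels (missing: %s)",
                paste(missing_cls, collapse = ", "))
  }
  n <- length(truth)
  rows <- lapply(classes, function(cl) {
    tp <- sum(truth == cl & predicted == cl)
    fn <- sum(truth == cl & predicted != cl)
    fp <- sum(truth != cl & predicted == cl)
    tn <- n - tp - fn - fp
    tibble::tibble(class = cl, TP = tp, FN = fn, TN = tn, FP = fp)
  })
  out <- dplyr::bind_rows(rows)
  rate <- function(num, den) {
    if (any(den == 0)) {
      warning("0/0 in a per-class rate; reporting 0 for that class", call. = FALSE)
    }
    ifelse(den == 0, 0, 100 * num / den)
  }
  out$sensitivity <- rate(out$TP, out$TP + out$FN)
  out$specificity <- rate(out$TN, out$TN + out$FP)
  out$precision <- rate(out$TP, out$TP + out$FP)
  out
}

#' Macro-averaged summary of per-class metrics
#'
#' Unweighted arithmetic means of the per-class sensitivity, specificity and
#' precision over the classes present in the truth labels (classes never seen
#' in truth are excluded from the averages), plus overall accuracy computed
#' from total correct over total items. A `weighted = TRUE` variant weights
#' each class by its prevalence in the truth labels.
#'
#' @param per_class A [confusion_counts()] tibble.
#' @param weighted Weight classes by truth prevalence instead of equally?
#' @return A one-row tibble: `macro_sensitivity`, `macro_specificity`,
#'   `macro_precision`, `accuracy`, `n_classes`, `n`.
#' @export
macro_average <- function(per_class, weighted = FALSE) {
  if (!is.data.frame(per_class) || nrow(per_class) == 0L) {
    abort_input("per_class must be a non-empty confusion_counts() table")
  }
  present <- per_class$TP + per_class$FN > 0
  pc <- per_class[present, , drop = FALSE]
  w <- if (weighted) (pc$TP + pc$FN) / sum(pc$TP + pc$FN) else rep(1 / nrow(pc), nrow(pc))
  n <- per_class$TP[1] + per_class$FN[1] + per_class$TN[1] + per_class$FP[1]
  tibble::tibble(
    macro_sensitivity = sum(w * pc$sensitivity),
    macro_specificity = sum(w * pc$specificity),
    macro_precision = sum(w * pc$precision),
    accuracy = 100 * sum(per_class$TP) / n,
    n_classes = nrow(pc),
    n = n
  )
}
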