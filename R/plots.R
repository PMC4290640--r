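# ggplot2 views of cross-validation results.

#' Plot per-class sensitivity and specificity of a CV result
#'
#' The per-feature-set bar layout used to compare extractors: one bar pair
#' per class.
#'
#' @param object A [cross_validate()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.kaap_cv <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$per_class[, c("class", "sensitivity", "specificity")],
    cols = c("sensitivity", "specificity"),
    names_to = "metric", values_to = "percent"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$class, y = .data$percent,
                                     fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(
      x = "fold class", y = "percent",
      title = sprintf("%d-fold CV%s: accuracy %.1f%%", object$n_folds,
                      if (is.null(object$extractor)) "" else
                        paste0(" (", object$extractor, ")"),
                      object$accuracy)
    ) +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal()
}

#' @export
ggplot2::autoplot

#' Compare glance summaries of several CV runs
#'
#' @param summaries A tibble of [glance.kaap_cv()] rows (e.g. from several
#'   extractors bound together).
#' @return A ggplot object: accuracy per extractor and fold count.
#' @export
plot_cv_comparison <- function(summaries) {
  ggplot2::ggplot(summaries,
                  ggplot2::aes(x = factor(.data$n_folds), y = .data$accuracy,
                               fill = .data$extractor)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "number of folds", y = "accuracy (%)") +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal()
}
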