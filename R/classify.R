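# RBF-kernel SVM classification of feature tables under stratified n-fold
# cross-validation with a nested grid search for (C, gamma). Training and
# prediction are delegated to libsvm via e1071; features are passed through
# unscaled.

#' SVM configuration
#'
#' Candidate grids for the complexity parameter C and the RBF width gamma,
#' plus the inner cross-validation depth of the grid search. The default grid
#' is the conventional libsvm search `log2(C) in \{-5, -3, ..., 15\}`,
#' `log2(gamma) in \{-15, -13, ..., 3\}`; `preset = "fast"` gives a coarse
#' 3 x 3 grid suitable for tests and small synthetic runs.
#'
#' @param log2_C Numeric vector of log2 candidate C values.
#' @param log2_gamma Numeric vector of log2 candidate gamma values.
#' @param inner_folds Stratified folds used by the inner grid-search CV.
#' @param preset `"default"` or `"fast"`; ignored when explicit grids are given.
#' @param global_grid If `TRUE`, [cross_validate()] runs one grid search on the
#'   full data before the outer CV instead of one per outer training split.
#' @return An object of class `svm_config`.
#' @export
svm_config <- function(log2_C = NULL, log2_gamma = NULL, inner_folds = 3L,
                       preset = c("default", "fast"), global_grid = FALSE) {
  preset <- match.arg(preset)
  if (is.null(log2_C)) {
    log2_C <- if (preset == "fast") c(-1, 5, 11) else seq(-5, 15, by = 2)
  }
  if (is.null(log2_gamma)) {
    log2_gamma <- if (preset == "fast") c(-13, -7, -1) else seq(-15, 3, by = 2)
  }
  if (length(log2_C) == 0L || length(log2_gamma) == 0L) {
    abort_input("hyperparameter grids must be non-empty")
  }
  structure(
    list(log2_C = sort(log2_C), log2_gamma = sort(log2_gamma),
         inner_folds = as.integer(inner_folds), global_grid = isTRUE(global_grid)),
    class = "svm_config"
  )
}

#' Deterministic stratified fold assignment
#'
#' Within each class, ids are shuffled by a generator seeded from `seed` and
#' dealt round-robin to the folds, so per-class fold counts differ by at most
#' one. The assignment is a pure function of (labels, n_folds, seed); classes
#' with fewer members than folds simply miss some folds.
#'
#' @param labels Named vector or factor: names (or a `protein_id`/`label`
#'   tibble) give protein ids, values give classes.
#' @param n_folds Number of folds, at least 2.
#' @param seed Integer seed.
#' @return A tibble with `protein_id`, `label`, `fold` (0-based fold index).
#' @export
stratified_folds <- function(labels, n_folds, seed = 1L) {
  if (n_folds < 2L) abort_input("n_folds must be at least 2")
  if (is.data.frame(labels)) {
    ids <- labels$protein_id
    cls <- as.character(labels$label)
  } else {
    ids <- names(labels)
    cls <- as.character(labels)
    if (is.null(ids)) ids <- as.character(seq_along(labels))
  }
  out <- withr::with_seed(seed, {
    pieces <- lapply(split(ids, cls), function(members) {
      members <- sample(members)
      tibble::tibble(protein_id = members,
                     fold = (seq_along(members) - 1L) %% n_folds)
    })
    dplyr::bind_rows(pieces, .id = "label")
  })
  out <- out[match(ids, out$protein_id), c("protein_id", "label", "fold")]
  tibble::as_tibble(out)
}

# Fit libsvm with fixed hyperparameters; x unscaled per the method.
fit_svm <- function(x, y, C, gamma) {
  e1071::svm(x = x, y = y, scale = FALSE, kernel = "radial",
             cost = C, gamma = gamma)
}

#' Grid search for (C, gamma)
#'
#' Exhaustively evaluates every grid point by stratified inner
#' cross-validation on the training data and returns the point with the
#' highest inner accuracy. Ties break to the smaller C, then the smaller
#' gamma.
#'
#' @param x Numeric feature matrix (rows = training items).
#' @param y Class labels (coerced to factor).
#' @param config An [svm_config()].
#' @param seed Integer seed for the inner fold assignment.
#' @return A list with `C`, `gamma`, `inner_accuracy` (percent), and the full
#'   `grid` tibble of evaluated points.
#' @export
grid_search <- function(x, y, config = svm_config(), seed = 1L) {
  y <- factor(y)
  if (nlevels(droplevels(y)) < 2L) {
    abort_input("grid search needs at least 2 classes in the training labels")
  }
  grid <- expand.grid(log2_gamma = config$log2_gamma, log2_C = config$log2_C)
  if (nrow(grid) == 1L) {
    return(list(C = 2^grid$log2_C, gamma = 2^grid$log2_gamma,
                inner_accuracy = NA_real_, grid = tibble::as_tibble(grid)))
  }
  n_inner <- min(config$inner_folds, min(table(y)))
  n_inner <- max(n_inner, 2L)
  folds <- stratified_folds(stats::setNames(as.character(y), seq_along(y)),
                            n_folds = n_inner, seed = seed)
  fold_of <- folds$fold[match(as.character(seq_along(y)), folds$protein_id)]

  grid$accuracy <- vapply(seq_len(nrow(grid)), function(g) {
    C <- 2^grid$log2_C[g]
    gamma <- 2^grid$log2_gamma[g]
    correct <- 0L
    for (f in sort(unique(fold_of))) {
      tr <- fold_of != f
      if (nlevels(droplevels(y[tr])) < 2L) next
      fit <- fit_svm(x[tr, , drop = FALSE], droplevels(y[tr]), C, gamma)
      pred <- stats::predict(fit, x[!tr, , drop = FALSE])
      correct <- correct + sum(as.character(pred) == as.character(y[!tr]))
    }
    100 * correct / length(y)
  }, numeric(1))

  best <- order(-grid$accuracy, grid$log2_C, grid$log2_gamma)[1]
  list(C = 2^grid$log2_C[best], gamma = 2^grid$log2_gamma[best],
       inner_accuracy = grid$accuracy[best], grid = tibble::as_tibble(grid))
}

#' Stratified n-fold cross-validation of an SVM on a feature table
#'
#' The protocol behind every reported accuracy: proteins are dealt into
#' stratified folds; for each fold a grid search (nested, on the training
#' split only) picks (C, gamma), an RBF SVM is fitted on the training split
#' and the held-out fold is predicted. Every protein is predicted exactly
#' once; features are used unscaled. With `config$global_grid = TRUE` a single
#' grid search on all data replaces the per-fold searches.
#'
#' @param features A feature tibble from [extract_features()] (columns
#'   `protein_id`, `label`, then features), or a numeric matrix plus `labels`.
#' @param n_folds Number of outer folds.
#' @param seed Integer seed controlling fold assignment and inner searches.
#' @param config An [svm_config()].
#' @param labels Optional label vector overriding the `label` column.
#' @return An object of class `kaap_cv`: list with `predictions` (tibble:
#'   `protein_id`, `label`, `fold`, `predicted`), `accuracy` (percent),
#'   `fold_params` (chosen C and gamma per fold), `per_class`
#'   ([confusion_counts()] tibble), `macro` ([macro_average()] row),
#'   `n_folds`, `seed`, and the config.
#' @export
cross_validate <- function(features, n_folds = 5L, seed = 1L,
                           config = svm_config(), labels = NULL) {
  if (is.matrix(features)) {
    x <- features
    ids <- rownames(x)
    if (is.null(ids)) ids <- as.character(seq_len(nrow(x)))
  } else {
    x <- feature_matrix(features)
    ids <- features$protein_id
    if (is.null(labels)) labels <- features$label
  }
  if (is.null(labels)) abort_input("labels are required")
  if (anyNA(x)) abort_input("feature matrix contains missing values")
  if (length(labels) != nrow(x)) {
    abort_input("labels (%d) and feature rows (%d) differ", length(labels), nrow(x))
  }
  y <- factor(as.character(labels))
  if (nlevels(y) < 2L) abort_input("classification needs at least 2 classes")

  folds <- stratified_folds(stats::setNames(as.character(y), ids),
                            n_folds = n_folds, seed = seed)
  fold_of <- folds$fold[match(ids, folds$protein_id)]

  global <- if (config$global_grid) {
    grid_search(x, y, config = config, seed = seed)
  } else NULL

  predicted <- character(length(y))
  fold_params <- list()
  for (f in sort(unique(fold_of))) {
    tr <- fold_of != f
    best <- if (is.null(global)) {
      grid_search(x[tr, , drop = FALSE], y[tr], config = config,
                  seed = seed + f + 1L)
    } else global
    fit <- fit_svm(x[tr, , drop = FALSE], droplevels(y[tr]), best$C, best$gamma)
    predicted[!tr] <- as.character(stats::predict(fit, x[!tr, , drop = FALSE]))
    fold_params[[length(fold_params) + 1L]] <- tibble::tibble(
      fold = f, C = best$C, gamma = best$gamma,
      inner_accuracy = best$inner_accuracy
    )
  }

  predictions <- tibble::tibble(
    protein_id = ids, label = as.character(y), fold = fold_of,
    predicted = predicted
  )
  per_class <- confusion_counts(predictions$label, predictions$predicted,
                                classes = levels(y))
  structure(
    list(
      predictions = predictions,
      accuracy = 100 * mean(predictions$predicted == predictions$label),
      fold_params = dplyr::bind_rows(fold_params),
      per_class = per_class,
      macro = macro_average(per_class),
      n_folds = as.integer(n_folds),
      seed = as.integer(seed),
      config = config,
      extractor = attr(features, "extractor")
    ),
    class = "kaap_cv"
  )
}

#' @export
print.kaap_cv <- function(x, ...) {
  cat(sprintf("<kaap_cv> %d-fold CV%s: accuracy %.1f%% (n = %d, %d classes, seed %d)\n",
              x$n_folds,
              if (is.null(x$extractor)) "" else paste0(" [", x$extractor, "]"),
              x$accuracy, nrow(x$predictions),
              nrow(x$per_class), x$seed))
  invisible(x)
}

#' Tidy per-class metrics of a cross-validation result
#'
#' @param x A [cross_validate()] result.
#' @param ... Unused.
#' @return The per-class [confusion_counts()] tibble.
#' @importFrom generics tidy
#' @export
tidy.kaap_cv <- function(x, ...) x$per_class

#' One-row summary of a cross-validation result
#'
#' @param x A [cross_validate()] result.
#' @param ... Unused.
#' @return A one-row tibble: extractor, folds, seed, accuracy, macro rates.
#' @importFrom generics glance
#' @export
glance.kaap_cv <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(
      extractor = if (is.null(x$extractor)) NA_character_ else x$extractor,
      n_folds = x$n_folds, seed = x$seed
    ),
    x$macro
  )
}

#' @export
generics::tidy

#' @export
generics::glance

#' Train a final fold classifier on a full feature table
#'
#' Runs a grid search on all rows, fits the RBF SVM, and stores the feature
#' layout so later predictions can be checked against it.
#'
#' @param features Feature tibble from [extract_features()].
#' @param config An [svm_config()].
#' @param seed Integer seed for the grid-search folds.
#' @return An object of class `kaap_model`.
#' @export
train_classifier <- function(features, config = svm_config(), seed = 1L) {
  x <- feature_matrix(features)
  y <- factor(features$label)
  best <- grid_search(x, y, config = config, seed = seed)
  structure(
    list(
      fit = fit_svm(x, y, best$C, best$gamma),
      C = best$C, gamma = best$gamma,
      feature_names = colnames(x),
      extractor = attr(features, "extractor"),
      k_max = attr(features, "k_max"),
      classes = levels(y)
    ),
    class = "kaap_model"
  )
}

#' Predict fold labels for new feature rows
#'
#' @param object A [train_classifier()] model.
#' @param new_features Feature tibble (or matrix) with the same feature layout
#'   the model was trained on; a dimensionality or name mismatch (e.g. k-AAP
#'   features built with a different `k_max`) is a versioning error.
#' @param ... Unused.
#' @return A tibble with `protein_id` and `predicted`.
#' @export
predict.kaap_model <- function(object, new_features, ...) {
  x <- if (is.matrix(new_features)) new_features else feature_matrix(new_features)
  if (ncol(x) != length(object$feature_names) ||
      (!is.null(colnames(x)) && !identical(colnames(x), object$feature_names))) {
    abort_input(paste0(
      "feature layout mismatch: model was trained on %d features",
      " (extractor %s, k_max %s) but input has %d"),
      length(object$feature_names),
      if (is.null(object$extractor)) "?" else object$extractor,
      if (is.null(object$k_max)) "?" else as.character(object$k_max),
      ncol(x))
  }
  ids <- if (is.matrix(new_features)) {
    rn <- rownames(new_features)
    if (is.null(rn)) as.character(seq_len(nrow(new_features))) else rn
  } else new_features$protein_id
  tibble::tibble(
    protein_id = ids,
    predicted = as.character(stats::predict(object$fit, x))
  )
}
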