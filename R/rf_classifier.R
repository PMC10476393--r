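#' Tune and train a random-forest group classifier
#'
#' Two-level classification of samples from taxon abundances, with the
#' out-of-bag (OOB) error driving both hyperparameters: for every candidate
#' `mtry` the OOB error at the largest tree count is averaged over
#' `repeats` refits, and the `mtry` with the lowest average wins (ties to
#' the smaller value); `ntree` is then the smallest scheduled tree count
#' whose OOB error is within `stability_epsilon` of the error at the full
#' schedule (the point where the forest has stabilised). Feature importance
#' is the classical pair of scores: OOB-permutation mean decrease in
#' accuracy (unscaled) and mean decrease in Gini impurity.
#'
#' @param features samples-by-taxa numeric matrix (or data frame) with
#'   taxon ids as column names
#' @param labels two-level factor (or character) of group membership,
#'   at least 4 samples per class
#' @param mtry_grid candidate numbers of variables per split; default
#'   `{floor(sqrt(p)/2), floor(sqrt(p)), 2 floor(sqrt(p)), floor(p/3)}`
#'   clipped to `[1, p]`
#' @param ntree_schedule increasing tree counts to consider
#' @param stability_epsilon OOB-error tolerance for the ntree rule
#' @param repeats refits averaged per mtry candidate
#' @param seed integer seed; the whole procedure is deterministic given it
#' @return a `forest_fit` object; see [tidy.forest_fit()],
#'   [glance.forest_fit()], [autoplot.forest_fit()]
#' @export
tune_and_train <- function(features, labels, mtry_grid = NULL,
                           ntree_schedule = seq(50L, 500L, by = 50L),
                           stability_epsilon = 0.01, repeats = 5,
                           seed = 1) {
  features <- as.matrix(features)
  if (ncol(features) == 0) {
    abort("no features", class = "keytaxa_validation_error")
  }
  if (anyNA(features)) {
    abort("features must not contain missing values",
          class = "keytaxa_validation_error")
  }
  labels <- factor(labels)
  if (nlevels(labels) != 2) {
    abort("labels must have exactly 2 classes",
          class = "keytaxa_validation_error")
  }
  if (any(table(labels) < 4)) {
    abort("each class needs at least 4 samples",
          class = "keytaxa_validation_error")
  }
  if (is.unsorted(ntree_schedule, strictly = TRUE)) {
    abort("ntree_schedule must be strictly increasing",
          class = "keytaxa_config_error")
  }
  p <- ncol(features)
  if (is.null(mtry_grid)) {
    s <- floor(sqrt(p))
    mtry_grid <- sort(unique(pmin(pmax(1L, c(floor(s / 2), s, 2L * s,
                                             floor(p / 3))), p)))
  }
  if (any(mtry_grid < 1 | mtry_grid > p)) {
    abort("mtry_grid values must lie in [1, n_features]",
          class = "keytaxa_config_error")
  }
  max_ntree <- max(ntree_schedule)

  tuning <- purrr::map_dfr(seq_along(mtry_grid), function(i) {
    errs <- vapply(seq_len(repeats), function(r) {
      set.seed(seed + 1000L * i + r)
      rf <- randomForest::randomForest(features, labels,
                                       mtry = mtry_grid[i],
                                       ntree = max_ntree)
      unname(rf$err.rate[max_ntree, "OOB"])
    }, numeric(1))
    tibble::tibble(mtry = mtry_grid[i], mean_oob_error = mean(errs))
  })
  best_mtry <- tuning$mtry[which.min(tuning$mean_oob_error)]

  set.seed(seed)
  full <- randomForest::randomForest(features, labels, mtry = best_mtry,
                                     ntree = max_ntree, importance = TRUE)
  curve <- tibble::tibble(ntree = seq_len(max_ntree),
                          oob_error = unname(full$err.rate[, "OOB"]))
  final_err <- curve$oob_error[max_ntree]
  stable <- ntree_schedule[
    abs(curve$oob_error[ntree_schedule] - final_err) <= stability_epsilon]
  best_ntree <- if (length(stable) > 0) min(stable) else max_ntree

  set.seed(seed)
  model <- randomForest::randomForest(features, labels, mtry = best_mtry,
                                      ntree = best_ntree, importance = TRUE)
  imp <- randomForest::importance(model, scale = FALSE)
  importance <- tibble::tibble(
    taxon_id = rownames(imp),
    mean_decrease_accuracy = unname(imp[, "MeanDecreaseAccuracy"]),
    mean_decrease_gini = unname(imp[, "MeanDecreaseGini"])
  ) %>%
    dplyr::arrange(dplyr::desc(.data$mean_decrease_accuracy))

  structure(
    list(model = model, mtry = best_mtry, ntree = best_ntree,
         oob_error = unname(model$err.rate[best_ntree, "OOB"]),
         oob_curve = curve, tuning = tuning, importance = importance,
         levels = levels(labels), seed = seed),
    class = "forest_fit"
  )
}

#' @export
print.forest_fit <- function(x, ...) {
  cat("Random-forest group classifier\n")
  cat(sprintf("  mtry = %d, ntree = %d, OOB error = %.2f%%\n",
              x$mtry, x$ntree, 100 * x$oob_error))
  cat("  classes:", paste(x$levels, collapse = " vs "), "\n")
  invisible(x)
}

#' Per-taxon importance of a fitted forest
#'
#' @param fit a `forest_fit`
#' @return tibble (taxon_id, mean_decrease_accuracy, mean_decrease_gini)
#'   sorted by decreasing mean decrease in accuracy
#' @export
oob_importance <- function(fit) {
  if (!inherits(fit, "forest_fit")) {
    abort("fit must be a forest_fit", class = "keytaxa_validation_error")
  }
  fit$importance
}

#' Evaluate a fitted forest on labelled samples
#'
#' @param fit a `forest_fit`
#' @param features samples-by-taxa matrix whose columns cover the taxa the
#'   model was trained on
#' @param labels true group labels
#' @return list with `accuracy` and a `confusion` tibble (truth,
#'   prediction, n)
#' @export
predict_eval <- function(fit, features, labels) {
  features <- as.matrix(features)
  if (nrow(features) == 0) {
    abort("empty evaluation set", class = "keytaxa_validation_error")
  }
  need <- rownames(randomForest::importance(fit$model))
  missing <- setdiff(need, colnames(features))
  if (length(missing) > 0) {
    abort(paste0("evaluation features missing taxa: ",
                 paste(utils::head(missing, 5), collapse = ", ")),
          class = "keytaxa_validation_error")
  }
  pred <- stats::predict(fit$model, features[, need, drop = FALSE])
  truth <- factor(labels, levels = fit$levels)
  conf <- tibble::as_tibble(table(truth = truth, prediction = pred),
                            .name_repair = "minimal")
  names(conf) <- c("truth", "prediction", "n")
  list(accuracy = mean(pred == truth), confusion = conf)
}

#' Tidy a forest fit
#'
#' @param x a `forest_fit`
#' @param ... unused
#' @return the importance tibble
#' @export
tidy.forest_fit <- function(x, ...) {
  x$importance
}

#' One-row summary of a forest fit
#'
#' @param x a `forest_fit`
#' @param ... unused
#' @export
glance.forest_fit <- function(x, ...) {
  tibble::tibble(mtry = x$mtry, ntree = x$ntree, oob_error = x$oob_error,
                 n_features = nrow(x$importance),
                 classes = paste(x$levels, collapse = "/"))
}

#' Importance dot plot of the top taxa
#'
#' @param object a `forest_fit`
#' @param top_n number of taxa to show
#' @param ... unused
#' @export
autoplot.forest_fit <- function(object, top_n = 30, ...) {
  df <- utils::head(object$importance, top_n) %>%
    tidyr::pivot_longer(c("mean_decrease_accuracy", "mean_decrease_gini"),
                        names_to = "score", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(
    .data$value,
    stats::reorder(.data$taxon_id, .data$value))) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~score, scales = "free_x") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
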