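#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a cross-validation result
#'
#' @param x A `habitat_cv` object.
#' @param ... Unused.
#' @return `tidy()`: per-fold metrics, one row per fold. `glance()`: one row
#'   with the fold means (and `auc_sd`), classifier and fold count.
#' @export
tidy.habitat_cv <- function(x, ...) x$folds

#' @rdname tidy.habitat_cv
#' @export
glance.habitat_cv <- function(x, ...) {
  s <- x$summary
  out <- tibble(classifier = x$classifier, n_folds = x$n_folds,
                selection = x$selection)
  for (i in seq_len(nrow(s))) out[[s$metric[i]]] <- s$mean[i]
  out$auc_sd <- s$sd[s$metric == "auc"]
  out
}

#' @rdname tidy.habitat_cv
#' @param object A `habitat_cv` object.
#' @export
autoplot.habitat_cv <- function(object, ...) {
  ggplot2::ggplot(object$roc,
                  ggplot2::aes(x = .data$fpr, y = .data$tpr,
                               colour = factor(.data$fold))) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey60") +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  colour = "Fold",
                  title = sprintf("ROC per held-out fold (%s)", object$classifier)) +
    ggplot2::theme_minimal()
}

#' Tidy a habitat clustering model
#'
#' @param x A `habitat_model`.
#' @param ... Unused.
#' @return `tidy()`: one row per habitat with standardized centroid channel
#'   values. `glance()`: one row with region, selected k and pooled voxel
#'   count.
#' @export
tidy.habitat_model <- function(x, ...) {
  as_tibble(x$centroids) |>
    dplyr::mutate(habitat = dplyr::row_number(), .before = 1) |>
    dplyr::mutate(region = x$region)
}

#' @rdname tidy.habitat_model
#' @export
glance.habitat_model <- function(x, ...) {
  tibble(region = x$region, k_selected = x$k_selected,
         k_min = min(x$sse_curve$k), k_max = max(x$sse_curve$k),
         n_voxels = x$n_voxels, seed = x$seed)
}

#' @rdname tidy.habitat_model
#' @param object A `habitat_model`.
#' @export
autoplot.habitat_model <- function(object, ...) {
  ggplot2::ggplot(object$sse_curve, ggplot2::aes(x = .data$k, y = .data$sse)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$k_selected, linetype = "dashed",
                        colour = "red") +
    ggplot2::scale_x_continuous(breaks = object$sse_curve$k) +
    ggplot2::labs(x = "Number of clusters k", y = "Within-cluster SSE",
                  title = sprintf("SSE elbow (%s): k = %d", object$region,
                                  object$k_selected)) +
    ggplot2::theme_minimal()
}

#' Tidy a SHAP explanation
#'
#' @param x A `shap_explanation`.
#' @param ... Unused.
#' @return `tidy()`: long tibble (row, feature, attribution). `glance()`:
#'   base value, row/feature counts, additivity residual.
#' @export
tidy.shap_explanation <- function(x, ...) {
  as_tibble(x$attributions) |>
    dplyr::mutate(row = dplyr::row_number(), .before = 1) |>
    tidyr::pivot_longer(-"row", names_to = "feature",
                        values_to = "attribution")
}

#' @rdname tidy.shap_explanation
#' @export
glance.shap_explanation <- function(x, ...) {
  tibble(
    base_value = x$base_value,
    n_rows = nrow(x$attributions),
    n_features = ncol(x$attributions),
    max_additivity_residual =
      max(abs(x$base_value + rowSums(x$attributions) - x$score))
  )
}

#' @rdname tidy.shap_explanation
#' @param object A `shap_explanation`.
#' @param top_n Features shown (default 15).
#' @export
autoplot.shap_explanation <- function(object, top_n = 15, ...) {
  imp <- utils::head(object$importance, top_n)
  imp$feature <- factor(imp$feature, levels = rev(imp$feature))
  ggplot2::ggplot(imp, ggplot2::aes(x = .data$importance, y = .data$feature)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Mean |SHAP attribution| (log-odds)", y = NULL,
                  title = "Global feature importance") +
    ggplot2::theme_minimal()
}

#' Tidy a model-suite result
#'
#' @param x A `habitat_suite`.
#' @param ... Unused.
#' @return The suite report: one row per model, columns = mean fold metrics.
#' @export
tidy.habitat_suite <- function(x, ...) x$report

#' @rdname tidy.habitat_suite
#' @param object A `habitat_suite`.
#' @export
autoplot.habitat_suite <- function(object, ...) {
  d <- object$report
  d$model <- factor(d$model, levels = d$model)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$model, y = .data$auc)) +
    ggplot2::geom_col() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "Mean held-out AUC") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
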