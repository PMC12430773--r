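#' Exact SHAP attributions for a linear classifier
#'
#' For a model that is linear in its (standardized) features, the Shapley
#' attribution of feature j for patient i has the closed form
#' `phi_ij = beta_j * (x_ij - mean(background_j))`, with base value equal to
#' the model score at the background means. Additivity
#' `base + sum_j(phi_ij) = score_i` then holds exactly for every row.
#' Attributions are computed on the linear-predictor (log-odds) scale.
#'
#' @param model A fitted `habitat_classifier` with `classifier = "lr"` (or any
#'   object with numeric `coefficients` and `intercept` fields). Nonlinear
#'   classifiers are rejected: use a model-agnostic explainer for those.
#' @param x Numeric matrix of (standardized) features to explain, columns
#'   matching the model's features.
#' @param background Numeric matrix of training rows defining the reference
#'   distribution (non-empty).
#' @return A `shap_explanation`: `base_value`, `attributions` (rows x
#'   features), `score` (linear predictor per row), `importance` tibble
#'   (mean absolute attribution per feature, descending).
#' @export
linear_shap <- function(model, x, background) {
  cf <- linear_coefficients(model)
  x <- as.matrix(x)
  background <- as.matrix(background)
  if (nrow(background) == 0) abort("`background` must be non-empty.")
  feats <- names(cf$beta)
  if (!all(feats %in% colnames(x)) || !all(feats %in% colnames(background))) {
    abort("`x`/`background` lack the model's feature columns.")
  }
  x <- x[, feats, drop = FALSE]
  bg_mean <- colMeans(background[, feats, drop = FALSE])
  phi <- sweep(x, 2, bg_mean) * rep(cf$beta, each = nrow(x))
  base <- cf$intercept + sum(cf$beta * bg_mean)
  score <- as.numeric(x %*% cf$beta) + cf$intercept
  imp <- tibble(
    feature = feats,
    importance = colMeans(abs(phi))
  ) |> dplyr::arrange(dplyr::desc(.data$importance), .data$feature)
  structure(
    list(base_value = base, attributions = phi, score = score,
         importance = imp),
    class = "shap_explanation"
  )
}

linear_coefficients <- function(model) {
  if (inherits(model, "habitat_classifier")) {
    if (model$classifier != "lr") {
      abort(paste0("SHAP in closed form needs a linear model; got '",
                   model$classifier,
                   "'. Use a model-agnostic explainer for nonlinear models."))
    }
    return(list(beta = model$fit$coefficients,
                intercept = model$fit$intercept))
  }
  if (!is.null(model$coefficients) && !is.null(model$intercept)) {
    return(list(beta = model$coefficients, intercept = model$intercept))
  }
  abort("cannot extract linear coefficients from `model`.")
}

#' @export
print.shap_explanation <- function(x, ...) {
  cat(sprintf("<shap_explanation> %d rows x %d features, base value %.4f\n",
              nrow(x$attributions), ncol(x$attributions), x$base_value))
  print(utils::head(x$importance, 5))
  invisible(x)
}

#' Rank features per fold and pool the top m across folds
#'
#' Orders each fold's features by global SHAP importance (mean absolute
#' attribution, descending; ties broken by feature name so the ranking is
#' run-to-run stable), takes the top `top_m` of each fold, and returns the
#' union with per-fold ranks retained.
#'
#' @param explanations List of `shap_explanation` objects, one per fold.
#' @param top_m Features taken from each fold (default 3).
#' @return A tibble: `feature`, `n_folds_top` (how many folds ranked it in
#'   their top m), `best_rank`, and per-fold rank columns `rank_fold*` (NA
#'   when the feature was absent from that fold's model).
#' @export
rank_and_pool <- function(explanations, top_m = 3) {
  if (length(explanations) < 1) abort("need at least one fold explanation.")
  if (top_m < 1) abort("`top_m` must be >= 1.")
  per_fold <- lapply(seq_along(explanations), function(f) {
    imp <- explanations[[f]]$importance
    imp$rank <- seq_len(nrow(imp))
    imp$fold <- f
    imp
  })
  top <- dplyr::bind_rows(lapply(per_fold, function(d) utils::head(d, top_m)))
  ranks <- dplyr::bind_rows(per_fold) |>
    dplyr::select("feature", "fold", "rank") |>
    tidyr::pivot_wider(names_from = "fold", values_from = "rank",
                       names_prefix = "rank_fold")
  pooled <- top |>
    dplyr::group_by(.data$feature) |>
    dplyr::summarise(n_folds_top = dplyr::n(), best_rank = min(.data$rank),
                     .groups = "drop") |>
    dplyr::arrange(.data$best_rank, dplyr::desc(.data$n_folds_top),
                   .data$feature)
  dplyr::left_join(pooled, ranks, by = "feature")
}

#' Association between a feature and dichotomized PD-L1 CPS
#'
#' Dichotomizes the combined positive score at `cps >= cutpoint` (the
#' boundary value goes to the high group) and compares feature values between
#' the CPS-high and CPS-low groups with a Welch two-sample t-test.
#'
#' @param values Numeric feature values.
#' @param cps Integer CPS scores, same length.
#' @param cutpoint Dichotomization threshold (default 15).
#' @param feature Feature name carried into the report.
#' @return A one-row tibble: `feature`, `test`, `statistic`, `p_value`,
#'   `significant` (p < 0.05), group sizes.
#' @export
cps_association <- function(values, cps, cutpoint = 15, feature = "feature") {
  stopifnot(length(values) == length(cps))
  high <- cps >= cutpoint
  if (!any(high) || all(high)) {
    abort(sprintf("empty CPS group after dichotomizing at %s (high n = %d, low n = %d).",
                  cutpoint, sum(high), sum(!high)))
  }
  tt <- stats::t.test(values[high], values[!high])
  tibble(
    feature = feature, test = "welch_t",
    statistic = unname(tt$statistic), p_value = tt$p.value,
    significant = tt$p.value < 0.05,
    n_high = sum(high), n_low = sum(!high)
  )
}

#' Pearson correlation between a feature and an immune-cell density
#'
#' @param values Numeric feature values.
#' @param densities Cell densities (cells per unit area), same length,
#'   n >= 3.
#' @param feature Feature name carried into the report.
#' @param strong_threshold Absolute correlation above which the association
#'   is flagged strong (default 0.75).
#' @return A one-row tibble: `feature`, `test`, `r`, `p_value`, `strong`
#'   (|r| > threshold), `significant` (p < 0.05), `n`.
#' @export
biomarker_correlation <- function(values, densities, feature = "feature",
                                  strong_threshold = 0.75) {
  stopifnot(length(values) == length(densities))
  if (length(values) < 3) abort("need at least 3 paired observations.")
  if (sd(values) == 0 || sd(densities) == 0) {
    abort("zero variance: Pearson correlation is undefined.")
  }
  ct <- stats::cor.test(values, densities, method = "pearson")
  tibble(
    feature = feature, test = "pearson",
    r = unname(ct$estimate), p_value = ct$p.value,
    strong = abs(unname(ct$estimate)) > strong_threshold,
    significant = ct$p.value < 0.05,
    n = length(values)
  )
}
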