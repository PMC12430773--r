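#' Pipeline configuration
#'
#' Validates and bundles every knob of the end-to-end habitat-radiomics
#' pipeline. All stage seeds derive deterministically from the master
#' `seed`, and the full configuration is serialized next to every output, so
#' re-running an identical configuration reproduces identical outputs.
#'
#' @param out_dir Output directory for reports and serialized models.
#' @param cohort A [cohort_config()] (simulation stage).
#' @param phantom A [phantom_config()].
#' @param target_spacing_mm Isotropic resampling target (default 1 mm).
#' @param ring_radius_mm Peritumoral ring radius (default 3 mm).
#' @param k_range Habitat candidate cluster counts (default 1:10).
#' @param n_bins Texture discretization bin count (default 32).
#' @param min_voxels Minimum subregion size for feature extraction.
#' @param cv_folds Cross-validation folds (default 5).
#' @param classifier Classifier id for the suite (default `"lr"`).
#' @param models Suite model ids to run (default: all nine).
#' @param pooled_selection If `TRUE`, feature selection is fitted once on all data
#'   before cross-validation ("pooled") instead of inside each fold.
#' @param bias_correct Run bias correction during preprocessing.
#' @param seed Master seed.
#' @return A validated `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("habitomics_"),
                            cohort = cohort_config(),
                            phantom = phantom_config(),
                            target_spacing_mm = 1,
                            ring_radius_mm = 3,
                            k_range = 1:10,
                            n_bins = 32,
                            min_voxels = 10,
                            cv_folds = 5,
                            classifier = "lr",
                            models = NULL,
                            pooled_selection = FALSE,
                            bias_correct = TRUE,
                            seed = 1L) {
  cfg <- list(out_dir = out_dir, cohort = cohort, phantom = phantom,
              target_spacing_mm = target_spacing_mm,
              ring_radius_mm = ring_radius_mm, k_range = as.integer(k_range),
              n_bins = as.integer(n_bins), min_voxels = as.integer(min_voxels),
              cv_folds = as.integer(cv_folds), classifier = classifier,
              models = models, pooled_selection = isTRUE(pooled_selection),
              bias_correct = isTRUE(bias_correct), seed = as.integer(seed))
  if (!is.numeric(target_spacing_mm) || target_spacing_mm <= 0) {
    abort("`target_spacing_mm` must be positive.")
  }
  if (!is.numeric(ring_radius_mm) || ring_radius_mm < 0) {
    abort("`ring_radius_mm` must be non-negative.")
  }
  if (length(cfg$k_range) < 3) abort("`k_range` needs at least 3 candidates.")
  if (cfg$n_bins < 2) abort("`n_bins` must be >= 2.")
  if (cfg$cv_folds < 2) abort("`cv_folds` must be >= 2.")
  if (!classifier %in% c("lr", "svm", "knn", "dt", "rf")) {
    abort("`classifier` must be one of lr, svm, knn, dt, rf.")
  }
  stopifnot(inherits(cohort, "cohort_config"), inherits(phantom, "phantom_config"))
  structure(cfg, class = "pipeline_config")
}

#' Run the end-to-end habitat-radiomics pipeline
#'
#' Executes simulate -> preprocess -> regions -> habitats -> features ->
#' modeling -> interpretation on a synthetic cohort and writes a report
#' bundle (metric CSVs, ROC/calibration points, confusion matrices, habitat
#' models, SHAP summaries, associations, and the configuration with all
#' seeds) under `config$out_dir`.
#'
#' @param config A [pipeline_config()].
#' @param keep_volumes Keep per-patient processed volumes in the returned
#'   bundle (memory-heavy; default `FALSE`).
#' @return Invisibly, the report bundle: a list with the cohort table, the
#'   two habitat models, the feature table, the `habitat_suite`, the decision
#'   model's SHAP pooling, and association tables.
#' @export
run_pipeline <- function(config = pipeline_config(), keep_volumes = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort_cfg <- config$cohort
  cohort_cfg$seed <- derive_seed(config$seed, "simulate")

  message("stage: simulate")
  cohort <- generate_cohort(cohort_cfg, phantom = config$phantom)

  message("stage: preprocess + regions")
  patients <- lapply(cohort$patients, function(p) {
    pp <- preprocess_patient(p$volumes, p$masks,
                             target_mm = config$target_spacing_mm,
                             bias_correct = config$bias_correct)
    ring <- make_peritumoral_ring(pp$masks$tumor, pp$masks$spacing_mm,
                                  radius_mm = config$ring_radius_mm,
                                  exclusion = pp$masks$exclusion)
    pp$masks <- region_masks(pp$masks$tumor, ring = ring,
                             exclusion = pp$masks$exclusion,
                             spacing_mm = pp$masks$spacing_mm)
    pp
  })
  names(patients) <- cohort$table$patient_id

  message("stage: habitats")
  models <- lapply(c(intratumoral = "intratumoral", peritumoral = "peritumoral"),
                   function(region) {
    pooled <- pool_voxels(patients, region)
    fit_habitat_model(pooled, region = region, k_range = config$k_range,
                      seed = derive_seed(config$seed, paste0("habitat-", region)))
  })
  if (models$intratumoral$k_selected != models$peritumoral$k_selected) {
    message(sprintf("note: elbow chose k=%d (intratumoral) vs k=%d (peritumoral).",
                    models$intratumoral$k_selected,
                    models$peritumoral$k_selected))
  }
  for (nm in names(patients)) {
    patients[[nm]]$label_maps <- list(
      intratumoral = assign_habitats(patients[[nm]]$volumes,
                                     patients[[nm]]$masks$tumor,
                                     models$intratumoral),
      peritumoral = assign_habitats(patients[[nm]]$volumes,
                                    patients[[nm]]$masks$ring,
                                    models$peritumoral)
    )
  }
  write_habitat_model(models$intratumoral,
                      file.path(config$out_dir, "habitat_model_intratumoral.json"))
  write_habitat_model(models$peritumoral,
                      file.path(config$out_dir, "habitat_model_peritumoral.json"))

  message("stage: features")
  k_feat <- max(models$intratumoral$k_selected, models$peritumoral$k_selected)
  features <- build_feature_table(patients, k = k_feat,
                                  n_bins = config$n_bins,
                                  min_voxels = config$min_voxels)
  clinical <- c("induction_cycles", "post_t", "agr")
  features <- dplyr::left_join(features,
                               cohort$table[c("patient_id", clinical)],
                               by = "patient_id")
  # a habitat index that exists in only one region's model yields columns
  # that are missing for every patient; they carry no information and are
  # dropped before imputation (which requires one observed value per column)
  all_na <- names(features)[vapply(features, function(v) all(is.na(v)),
                                   logical(1))]
  if (length(all_na)) {
    message(sprintf("dropping %d structurally missing feature column(s).",
                    length(all_na)))
    features <- features[setdiff(names(features), all_na)]
  }
  write_feature_table(features, file.path(config$out_dir, "feature_table.csv"),
                      n_bins = config$n_bins, min_voxels = config$min_voxels)

  message("stage: modeling")
  labels <- cohort$table$label
  suite <- build_model_suite(
    features, labels, clinical_candidates = clinical,
    models = config$models, classifier = config$classifier,
    n_folds = config$cv_folds,
    selection = if (config$pooled_selection) "pooled" else "fold",
    seed = derive_seed(config$seed, "modeling")
  )
  utils::write.csv(suite$report, file.path(config$out_dir, "model_report.csv"),
                   row.names = FALSE)
  for (nm in names(suite$models)) {
    ev <- suite$models[[nm]]
    safe <- gsub("[^A-Za-z0-9]", "_", nm)
    utils::write.csv(ev$folds,
                     file.path(config$out_dir, sprintf("folds_%s.csv", safe)),
                     row.names = FALSE)
    utils::write.csv(ev$roc,
                     file.path(config$out_dir, sprintf("roc_%s.csv", safe)),
                     row.names = FALSE)
    utils::write.csv(ev$calibration,
                     file.path(config$out_dir, sprintf("calibration_%s.csv", safe)),
                     row.names = FALSE)
    jsonlite::write_json(ev$confusion,
                         file.path(config$out_dir, sprintf("confusion_%s.json", safe)),
                         auto_unbox = TRUE, digits = NA)
  }

  message("stage: interpretation")
  interpretation <- NULL
  decision_id <- if ("Decision" %in% names(suite$models)) "Decision" else names(suite$models)[1]
  if (config$classifier == "lr") {
    interpretation <- explain_suite_model(suite$models[[decision_id]],
                                          cohort$table)
    utils::write.csv(interpretation$pooled,
                     file.path(config$out_dir, "shap_key_features.csv"),
                     row.names = FALSE)
    if (!is.null(interpretation$associations)) {
      utils::write.csv(interpretation$associations,
                       file.path(config$out_dir, "associations.csv"),
                       row.names = FALSE)
    }
  }

  cfg_json <- config
  cfg_json$models <- cfg_json$models %||% "all"
  jsonlite::write_json(
    lapply(unclass(cfg_json), function(v) if (is.list(v)) unclass(v) else v),
    file.path(config$out_dir, "pipeline_config.json"),
    auto_unbox = TRUE, digits = NA, force = TRUE
  )

  bundle <- list(
    cohort = cohort$table, habitat_models = models,
    features = features, suite = suite, interpretation = interpretation,
    out_dir = config$out_dir
  )
  if (keep_volumes) bundle$patients <- patients
  invisible(bundle)
}

#' Explain a cross-validated linear model and screen biomarker associations
#'
#' Computes per-fold linear SHAP explanations of a cross-validated logistic
#' model (background: the fold's training rows; explained: all rows in the
#' fold's standardized design), pools the top-`top_m` features of every fold
#' with [rank_and_pool()], and — when the cohort table carries `cps` and
#' `cd45_stroma` columns — screens each pooled key feature against
#' dichotomized PD-L1 CPS (Welch t at CPS >= 15) and against stromal CD45+
#' density (Pearson, strong at |r| > 0.75).
#'
#' @param cv A `habitat_cv` fitted with `classifier = "lr"`.
#' @param cohort_table Cohort tibble with `patient_id` and optional `cps` /
#'   `cd45_stroma` columns.
#' @param top_m Features pooled per fold (default 3).
#' @return A list: `shap` (per-fold `shap_explanation`s), `pooled` (key
#'   features), `associations` (tibble or `NULL`).
#' @export
explain_suite_model <- function(cv, cohort_table, top_m = 3) {
  stopifnot(inherits(cv, "habitat_cv"))
  shaps <- list()
  for (f in seq_along(cv$fits)) {
    fit <- cv$fits[[f]]
    if (is.null(fit$classifier) || fit$classifier$classifier != "lr") next
    if (ncol(fit$x_train) == 0) next
    shaps[[length(shaps) + 1]] <-
      linear_shap(fit$classifier, rbind(fit$x_train, fit$x_test),
                  fit$x_train)
  }
  if (!length(shaps)) return(NULL)
  pooled <- rank_and_pool(shaps, top_m = top_m)

  associations <- NULL
  if (all(c("cps", "cd45_stroma") %in% names(cohort_table))) {
    ord <- match(cv$ids, cohort_table$patient_id)
    rows <- list()
    for (feat in pooled$feature) {
      vals <- cv$data[[feat]]
      if (is.null(vals)) next
      ok <- !is.na(vals) & !is.na(ord)
      cps <- cohort_table$cps[ord[ok]]
      cd45 <- cohort_table$cd45_stroma[ord[ok]]
      v <- vals[ok]
      if (length(v) >= 3 && any(cps >= 15) && any(cps < 15)) {
        rows[[length(rows) + 1]] <-
          cps_association(v, cps, cutpoint = 15, feature = feat) |>
          dplyr::mutate(target = "cps", .before = 1)
      }
      if (length(v) >= 3 && sd(v) > 0 && sd(cd45) > 0) {
        rows[[length(rows) + 1]] <-
          biomarker_correlation(v, cd45, feature = feat) |>
          dplyr::mutate(target = "cd45_stroma", .before = 1)
      }
    }
    if (length(rows)) associations <- dplyr::bind_rows(rows)
  }
  list(shap = shaps, pooled = pooled, associations = associations)
}
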