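#' Assemble the cohort radiomic feature table
#'
#' For every patient x region x habitat x sequence, extracts the 107-feature
#' panel on the habitat subregion and assembles one wide tibble. Columns
#' follow the `{P|I}_{T1|T2|T1C}_h{n}_{Class}_{FeatureName}` naming scheme
#' (`I` = intratumoral, `P` = peritumoral). A habitat absent (or too small)
#' in a patient's region yields missing cells for that patient, never dropped
#' columns, so downstream imputation sees a rectangular table. With k = 5 in
#' both regions there are 10 subregions x 107 = 1070 radiomic columns per
#' sequence.
#'
#' @param patients List of per-patient lists with `volumes` (an
#'   [multiseq_volume()]) and `label_maps`: a list with entries
#'   `intratumoral` and `peritumoral`, each an integer habitat label map from
#'   [assign_habitats()]. Names are used as patient ids when present.
#' @param k Number of habitats (must be common to the cohort; guaranteed when
#'   label maps come from one cohort-level model per region).
#' @param n_bins,min_voxels Passed to [extract_features()].
#' @return A tibble: `patient_id` plus `2 * k * 3 * 107` radiomic columns.
#' @export
build_feature_table <- function(patients, k, n_bins = 32, min_voxels = 10) {
  ids <- names(patients) %||% sprintf("P%03d", seq_along(patients))
  region_codes <- c(intratumoral = "I", peritumoral = "P")
  seq_codes <- c(t1 = "T1", t2 = "T2", t1c = "T1C")

  rows <- lapply(seq_along(patients), function(pi) {
    p <- patients[[pi]]
    sp <- p$volumes$spacing_mm
    vals <- list()
    for (region in names(region_codes)) {
      lmap <- p$label_maps[[region]]
      if (is.null(lmap)) {
        abort(sprintf("patient %s lacks a %s label map.", ids[pi], region))
      }
      if (max(lmap) > k) {
        abort(sprintf("patient %s has habitat labels above k = %d.", ids[pi], k))
      }
      for (h in seq_len(k)) {
        submask <- lmap == h
        for (s in names(seq_codes)) {
          fv <- extract_features(p$volumes[[s]], submask, spacing_mm = sp,
                                 n_bins = n_bins, min_voxels = min_voxels)
          names(fv) <- sprintf("%s_%s_h%d_%s", region_codes[[region]],
                               seq_codes[[s]], h, names(fv))
          vals[[length(vals) + 1]] <- fv
        }
      }
    }
    c(patient_id = ids[pi], as.list(unlist(vals)))
  })
  dplyr::bind_rows(lapply(rows, as_tibble))
}

#' Parse feature-table column names back to their components
#'
#' @param columns Character vector of radiomic column names following the
#'   `{P|I}_{T1|T2|T1C}_h{n}_{Class}_{FeatureName}` scheme.
#' @return A tibble with columns `column`, `region` (I/P), `sequence`,
#'   `habitat` (integer), `class`, `feature`.
#' @export
parse_feature_columns <- function(columns) {
  m <- regmatches(columns,
                  regexec("^([IP])_(T1C|T1|T2)_h([0-9]+)_([A-Za-z]+)_(.+)$",
                          columns))
  bad <- vapply(m, length, integer(1)) != 6
  if (any(bad)) {
    abort(sprintf("column names do not follow the naming scheme: %s",
                  paste(columns[bad], collapse = ", ")))
  }
  tibble(
    column = columns,
    region = vapply(m, `[`, character(1), 2),
    sequence = vapply(m, `[`, character(1), 3),
    habitat = as.integer(vapply(m, `[`, character(1), 4)),
    class = vapply(m, `[`, character(1), 5),
    feature = vapply(m, `[`, character(1), 6)
  )
}

#' Write/read a feature table as CSV with a sidecar JSON schema
#'
#' @param table Feature table from [build_feature_table()].
#' @param path CSV path; the schema goes to `<path>.schema.json`.
#' @param n_bins,min_voxels Extraction settings recorded in the schema.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path, n_bins = 32, min_voxels = 10) {
  utils::write.csv(table, path, row.names = FALSE)
  radio <- grep("^[IP]_(T1C|T1|T2)_h[0-9]+_", names(table), value = TRUE)
  schema <- list(
    columns = parse_feature_columns(radio),
    bin_count = n_bins,
    min_voxels = min_voxels,
    extractor = paste0("habitomics ", as.character(utils::packageVersion("habitomics")))
  )
  jsonlite::write_json(schema, paste0(path, ".schema.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  as_tibble(utils::read.csv(path, check.names = FALSE))
}
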