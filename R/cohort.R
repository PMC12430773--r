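#' Cohort configuration for the synthetic phantom generator
#'
#' Controls cohort size, outcome prevalence, and how the binary outcome
#' (pathologic complete response, pCR) is linked to intratumoral habitat
#' composition. The default prevalence of 0.264 reflects a typical clinical
#' setting in which roughly one quarter of patients achieve pCR after neoadjuvant
#' chemoimmunotherapy.
#'
#' Outcome linkage: each patient receives a latent score
#' `s = effect_vector . intratumoral_fractions + logistic noise`; the
#' `round(n_patients * prevalence)` patients with the highest scores are
#' labelled positive. This makes the positive class exactly the requested
#' size (which keeps fold stratification exact) while still shifting the
#' habitat-fraction profile of positives along `effect_vector`. With
#' `effect_vector = 0` the labels are pure noise.
#'
#' @param n_patients Number of patients (>= 2). Default 20.
#' @param prevalence Target fraction of positive labels, in (0, 1).
#' @param effect_vector Per-habitat log-odds coefficients on intratumoral
#'   habitat volume fractions (length = number of classes). The default plants
#'   a strong effect on habitat h2 (habitat fractions have s.d. of a few
#'   percent, so a coefficient of 60 moves the latent log-odds by roughly 3
#'   standard deviations).
#' @param outcome_noise Scale of the logistic noise on the latent score.
#' @param clinical_spec,biomarker_spec Lists of distribution parameters; see
#'   [default_clinical_spec()] and [default_biomarker_spec()].
#' @param seed Integer RNG seed; fixing it makes the cohort byte-identical
#'   across runs.
#' @return A validated `cohort_config` list.
#' @export
cohort_config <- function(n_patients = 20L,
                          prevalence = 0.264,
                          effect_vector = c(0, 60, 0, 0, 0),
                          outcome_noise = 1,
                          clinical_spec = default_clinical_spec(),
                          biomarker_spec = default_biomarker_spec(),
                          seed = 1L) {
  cfg <- list(
    n_patients = as.integer(n_patients), prevalence = prevalence,
    effect_vector = as.numeric(effect_vector), outcome_noise = outcome_noise,
    clinical_spec = clinical_spec, biomarker_spec = biomarker_spec,
    seed = as.integer(seed)
  )
  if (is.na(cfg$n_patients) || cfg$n_patients < 2) {
    abort("`n_patients` must be >= 2.")
  }
  if (!is.numeric(prevalence) || prevalence <= 0 || prevalence >= 1) {
    abort("`prevalence` must lie strictly between 0 and 1.")
  }
  if (cfg$outcome_noise < 0) abort("`outcome_noise` must be non-negative.")
  structure(cfg, class = "cohort_config")
}

#' Default clinical covariate distributions
#'
#' Three clinical candidates commonly carried into response-prediction
#' decision model: number of induction cycles (ordinal 1-5), post-treatment T
#' stage (ordinal 0-5) and albumin-globulin ratio (AGR, continuous). Each has
#' a mild planted association with the outcome via label-conditional
#' distributions.
#'
#' @return A list of sampling parameters consumed by [generate_cohort()].
#' @export
default_clinical_spec <- function() {
  list(
    induction_cycles = list(
      pos = c(0.05, 0.45, 0.40, 0.02, 0.08),  # levels 1..5
      neg = c(0.01, 0.55, 0.37, 0.06, 0.01)
    ),
    post_t = list(
      pos = c(0.14, 0.07, 0.11, 0.50, 0.11, 0.07),  # stages T0..T4b
      neg = c(0.15, 0.12, 0.24, 0.22, 0.15, 0.12)
    ),
    agr = list(pos = c(mean = 1.5, sd = 0.2), neg = c(mean = 1.6, sd = 0.2))
  )
}

#' Default biomarker linkage
#'
#' PD-L1 combined positive score (CPS, non-negative integer) is coupled to the
#' intratumoral h2 fraction through a Poisson rate; immune-cell densities
#' (CD45+/CD3+/CD19+ in tumor and stroma, cells per unit area) are linearly
#' coupled to the peritumoral h2 fraction, and the stromal CD45+ density gets
#' an additive shift (in units of the density noise s.d.) in
#' positive-outcome patients.
#'
#' @param cps_base Baseline Poisson rate for CPS.
#' @param cps_coupling CPS rate change per unit intratumoral h2 fraction.
#' @param density_base Named baseline densities for cd45, cd3, cd19.
#' @param stroma_factor Multiplier applied to baselines in the stroma.
#' @param coupling Linear density change per unit peritumoral h2 fraction.
#' @param noise_sd Additive Gaussian noise s.d. on densities.
#' @param cd45_stroma_shift Outcome shift of stromal CD45+ density, in noise
#'   s.d. units.
#' @return A list of parameters consumed by [generate_biomarkers()].
#' @export
default_biomarker_spec <- function(cps_base = 12, cps_coupling = 60,
                                   density_base = c(cd45 = 800, cd3 = 400, cd19 = 150),
                                   stroma_factor = 1.5,
                                   coupling = 3000, noise_sd = 150,
                                   cd45_stroma_shift = 1) {
  if (any(density_base < 0) || noise_sd < 0 || cps_base < 0 || stroma_factor < 0) {
    abort("density parameters must be non-negative.")
  }
  list(cps_base = cps_base, cps_coupling = cps_coupling,
       density_base = density_base, stroma_factor = stroma_factor,
       coupling = coupling, noise_sd = noise_sd,
       cd45_stroma_shift = cd45_stroma_shift)
}

#' Generate a synthetic phantom cohort
#'
#' Generates `n_patients` phantoms (see [generate_phantom()]), links a binary
#' pCR outcome to intratumoral habitat composition, and attaches clinical
#' covariates and biomarkers. Exactly `round(n_patients * prevalence)`
#' patients are positive. Identical configuration and seed reproduce the
#' cohort byte-for-byte.
#'
#' @param config A [cohort_config()].
#' @param phantom A [phantom_config()] shared by all patients (semi-axes and
#'   shell boundaries are jittered per patient inside the generator).
#' @param render If `FALSE`, skip intensity rendering; masks, truth labels,
#'   habitat fractions, outcome, clinical covariates and biomarkers are still
#'   produced. Use this fast path when only the tabular layer is needed.
#' @return A list with `patients` (per-patient list of `volumes`, `masks`,
#'   `truth`) and `table`: a tibble with one row per patient (patient_id,
#'   label, clinical covariates, biomarkers, and true habitat volume
#'   fractions `I_frac_h*` / `P_frac_h*`).
#' @export
generate_cohort <- function(config = cohort_config(),
                            phantom = phantom_config(),
                            render = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  stopifnot(inherits(phantom, "phantom_config"))
  k <- phantom$n_classes
  if (length(config$effect_vector) != k) {
    abort(sprintf("`effect_vector` must have length n_classes = %d.", k))
  }
  n <- config$n_patients

  with_seed(config$seed, {
    patient_seeds <- sample.int(2147483646L, n)
    noise <- rlogis(n, location = 0, scale = config$outcome_noise)
    clin_seed <- sample.int(2147483646L, 1)
    bio_seed <- sample.int(2147483646L, 1)
  })

  patients <- lapply(seq_len(n), function(i) {
    generate_phantom(phantom, seed = patient_seeds[i], render = render)
  })

  frac_mat <- function(region) {
    t(vapply(patients, function(p) {
      f <- p$truth$fractions
      f$fraction[f$region == region]
    }, numeric(k)))
  }
  fi <- frac_mat("intratumoral")
  fp <- frac_mat("peritumoral")

  score <- as.vector(fi %*% config$effect_vector) + noise
  m <- round(n * config$prevalence)
  if (m < 1 || m > n - 1) {
    abort("prevalence and n_patients give an empty outcome class.")
  }
  label <- integer(n)
  label[order(score, decreasing = TRUE)[seq_len(m)]] <- 1L

  clinical <- with_seed(clin_seed, {
    cs <- config$clinical_spec
    draw_ord <- function(spec, levels) {
      vapply(label, function(l) {
        p <- if (l == 1) spec$pos else spec$neg
        sample(levels, 1, prob = p)
      }, numeric(1))
    }
    tibble(
      induction_cycles = draw_ord(cs$induction_cycles, 1:5),
      post_t = draw_ord(cs$post_t, 0:5),
      agr = ifelse(label == 1,
                   rnorm(n, cs$agr$pos["mean"], cs$agr$pos["sd"]),
                   rnorm(n, cs$agr$neg["mean"], cs$agr$neg["sd"]))
    )
  })

  truth_tbl <- tibble(
    patient_id = sprintf("P%03d", seq_len(n)),
    label = label
  )
  colnames(fi) <- paste0("I_frac_h", seq_len(k))
  colnames(fp) <- paste0("P_frac_h", seq_len(k))
  truth_tbl <- dplyr::bind_cols(truth_tbl, clinical,
                                as_tibble(fi), as_tibble(fp))

  h2 <- min(2L, k)
  biomarkers <- generate_biomarkers(
    truth_tbl,
    spec = config$biomarker_spec,
    seed = bio_seed,
    intratumoral_fraction = truth_tbl[[paste0("I_frac_h", h2)]],
    peritumoral_fraction = truth_tbl[[paste0("P_frac_h", h2)]]
  )
  truth_tbl <- dplyr::bind_cols(truth_tbl, biomarkers)

  list(patients = patients, table = truth_tbl)
}

#' Generate biomarker records from ground-truth habitat fractions
#'
#' Produces a PD-L1 CPS (integer >= 0) coupled to an intratumoral habitat
#' fraction, and CD45+/CD3+/CD19+ cell densities (cells per unit area,
#' truncated at 0) in tumor and stroma compartments linearly coupled to a
#' peritumoral habitat fraction. The stromal CD45+ density additionally shifts
#' upward in positive-outcome patients by `cd45_stroma_shift` noise s.d.
#'
#' @param truth Tibble with at least a `label` column (0/1 outcome).
#' @param spec Parameter list from [default_biomarker_spec()].
#' @param seed Integer RNG seed.
#' @param intratumoral_fraction,peritumoral_fraction Numeric vectors (one
#'   value per patient): the habitat fractions the biomarkers couple to.
#' @return A tibble with columns `cps`, and `<marker>_<compartment>` densities
#'   for marker cd45/cd3/cd19 and compartment tumor/stroma.
#' @export
generate_biomarkers <- function(truth, spec = default_biomarker_spec(),
                                seed = 1,
                                intratumoral_fraction,
                                peritumoral_fraction) {
  if (any(spec$density_base < 0) || spec$noise_sd < 0 || spec$cps_base < 0) {
    abort("density parameters must be non-negative.")
  }
  n <- nrow(truth)
  stopifnot(length(intratumoral_fraction) == n,
            length(peritumoral_fraction) == n)
  with_seed(seed, {
    lam <- pmax(0.1, spec$cps_base +
                  spec$cps_coupling * (intratumoral_fraction -
                                         mean(intratumoral_fraction)))
    cps <- rpois(n, lam)
    fdev <- peritumoral_fraction - mean(peritumoral_fraction)
    out <- tibble(cps = cps)
    for (marker in names(spec$density_base)) {
      for (comp in c("tumor", "stroma")) {
        base <- spec$density_base[[marker]] *
          if (comp == "stroma") spec$stroma_factor else 1
        d <- base + spec$coupling * fdev + rnorm(n, 0, spec$noise_sd)
        if (marker == "cd45" && comp == "stroma") {
          d <- d + spec$cd45_stroma_shift * spec$noise_sd * truth$label
        }
        out[[paste0(marker, "_", comp)]] <- pmax(d, 0)
      }
    }
    out
  })
}

#' Write a cohort to disk (NIfTI volumes/masks + cohort CSV + config JSON)
#'
#' @param cohort Result of [generate_cohort()] (rendered).
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tbl <- cohort$table
  for (i in seq_len(nrow(tbl))) {
    p <- cohort$patients[[i]]
    prefix <- file.path(dir, tbl$patient_id[i])
    if (!is.null(p$volumes)) write_msvol(p$volumes, prefix)
    write_mask(p$masks$tumor, paste0(prefix, "_tumor.nii"),
               p$masks$spacing_mm)
    if (!is.null(p$masks$exclusion)) {
      write_mask(p$masks$exclusion, paste0(prefix, "_exclusion.nii"),
                 p$masks$spacing_mm)
    }
  }
  utils::write.csv(tbl, file.path(dir, "cohort.csv"), row.names = FALSE)
  invisible(dir)
}
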