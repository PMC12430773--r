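# Shared fixtures, built in code. Heavy objects are cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# small, fast phantom configuration for tests that only need plumbing
small_phantom <- function(...) {
  phantom_config(grid_shape = c(28L, 28L, 20L), spacing_mm = c(2.5, 2.5, 2.5),
                 tumor_semiaxes_mm = c(12, 10, 8), ...)
}

# a rendered 4-patient cohort on the small grid, with rings attached
small_cohort <- function() {
  cached("small_cohort", {
    co <- generate_cohort(cohort_config(n_patients = 4, prevalence = 0.3,
                                        seed = 7),
                          phantom = small_phantom())
    co$patients <- lapply(co$patients, function(p) {
      p$masks <- region_masks(p$masks$tumor, ring = p$truth$ring,
                              exclusion = p$masks$exclusion,
                              spacing_mm = p$masks$spacing_mm)
      p
    })
    names(co$patients) <- co$table$patient_id
    co
  })
}

# habitat label maps straight from the generator's ground truth: a valid
# input to build_feature_table without fitting a clustering model
truth_label_maps <- function(patient) {
  lm_i <- patient$truth$label_map * (patient$masks$tumor > 0)
  lm_p <- patient$truth$label_map * (patient$truth$ring > 0)
  list(intratumoral = lm_i, peritumoral = lm_p)
}

# brute-force ring oracle: exhaustive distance threshold over all voxel pairs
ring_oracle <- function(tumor, spacing, radius, exclusion = NULL) {
  dims <- dim(tumor)
  idx_all <- which(array(TRUE, dims), arr.ind = TRUE)
  idx_tum <- which(tumor > 0, arr.ind = TRUE)
  co_all <- sweep(idx_all - 1, 2, spacing, "*")
  co_tum <- sweep(idx_tum - 1, 2, spacing, "*")
  ring <- array(FALSE, dims)
  for (i in seq_len(nrow(co_all))) {
    d2 <- (co_tum[, 1] - co_all[i, 1])^2 + (co_tum[, 2] - co_all[i, 2])^2 +
      (co_tum[, 3] - co_all[i, 3])^2
    dmin <- sqrt(min(d2))
    ring[idx_all[i, 1], idx_all[i, 2], idx_all[i, 3]] <-
      dmin > 0 && dmin <= radius + 1e-9
  }
  if (!is.null(exclusion)) ring <- ring & !(exclusion > 0)
  ring
}

# independent texture oracle: explicit per-voxel double loops (no block
# shifting), mirroring the symmetric per-direction GLCM definition
glcm_oracle_contrast <- function(gl) {
  dirs <- rbind(habitomics:::unique_directions_3d())
  dims <- dim(gl)
  idx <- which(!is.na(gl), arr.ind = TRUE)
  vals <- numeric(0)
  for (di in seq_len(nrow(dirs))) {
    d <- dirs[di, ]
    pairs <- matrix(0, 0, 2)
    for (r in seq_len(nrow(idx))) {
      nb <- idx[r, ] + d
      if (all(nb >= 1) && all(nb <= dims) && !is.na(gl[nb[1], nb[2], nb[3]])) {
        pairs <- rbind(pairs,
                       c(gl[idx[r, 1], idx[r, 2], idx[r, 3]],
                         gl[nb[1], nb[2], nb[3]]))
      }
    }
    if (nrow(pairs) == 0) next
    both <- rbind(pairs, pairs[, 2:1, drop = FALSE])
    vals <- c(vals, mean((both[, 1] - both[, 2])^2))
  }
  mean(vals)
}
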