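test_that("phantom construction: tumor inside grid, labels in range, fractions sum to 1", {
  ph <- generate_phantom(small_phantom(), seed = 3)
  tum <- ph$masks$tumor
  expect_gt(sum(tum), 0)
  # strictly interior: no tumor voxel on any grid face
  dims <- dim(tum)
  expect_false(any(tum[c(1, dims[1]), , ]))
  expect_false(any(tum[, c(1, dims[2]), ]))
  expect_false(any(tum[, , c(1, dims[3])]))
  expect_true(all(ph$truth$label_map %in% 1:5))
  sums <- tapply(ph$truth$fractions$fraction, ph$truth$fractions$region, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  expect_true(all(ph$truth$fractions$fraction >= 0))
})

test_that("noise-free, bias-free phantom reproduces the class mean triples exactly", {
  cfg <- small_phantom(noise_sd = 0, bias_amplitude = 0, class_sd = 0)
  ph <- generate_phantom(cfg, seed = 11)
  vols <- list(ph$volumes$t1, ph$volumes$t2, ph$volumes$t1c)
  for (h in 1:5) {
    sel <- ph$truth$label_map == h
    for (s in 1:3) {
      expect_identical(unique(vols[[s]][sel]), cfg$class_means[h, s])
    }
  }
})

test_that("tumor that cannot fit in the grid is rejected", {
  expect_error(phantom_config(grid_shape = c(16, 16, 12), spacing_mm = c(1, 1, 1),
                              tumor_semiaxes_mm = c(16, 14, 10)),
               "does not fit")
})

test_that("cohort labels hit the target count exactly for any (n, prevalence)", {
  cases <- list(c(212, 0.264, 56), c(20, 0.264, 5), c(60, 0.5, 30),
                c(15, 0.333, 5))
  for (cs in cases) {
    co <- generate_cohort(cohort_config(n_patients = cs[1], prevalence = cs[2],
                                        seed = 4),
                          phantom = small_phantom(), render = FALSE)
    expect_identical(sum(co$table$label), as.integer(cs[3]))
  }
})

test_that("identical configuration and seed reproduce the cohort exactly", {
  cfg <- cohort_config(n_patients = 3, prevalence = 0.34, seed = 21)
  a <- generate_cohort(cfg, phantom = small_phantom())
  b <- generate_cohort(cfg, phantom = small_phantom())
  expect_identical(a$table, b$table)
  expect_identical(a$patients[[2]]$volumes$t1c, b$patients[[2]]$volumes$t1c)
  expect_identical(a$patients[[3]]$truth$label_map, b$patients[[3]]$truth$label_map)
})

test_that("degenerate cohort configurations are rejected", {
  expect_error(cohort_config(n_patients = 0), "n_patients")
  expect_error(cohort_config(prevalence = 0), "prevalence")
  expect_error(cohort_config(prevalence = 1.2), "prevalence")
  expect_error(generate_cohort(cohort_config(effect_vector = c(1, 2)),
                               phantom = small_phantom(), render = FALSE),
               "effect_vector")
})

test_that("positive patients are shifted along the effect vector", {
  co <- generate_cohort(cohort_config(n_patients = 40, prevalence = 0.4,
                                      effect_vector = c(0, 60, 0, 0, 0),
                                      seed = 5),
                        phantom = small_phantom(), render = FALSE)
  t <- co$table
  expect_gt(mean(t$I_frac_h2[t$label == 1]), mean(t$I_frac_h2[t$label == 0]))
})

test_that("biomarker coupling behaves at its null and noise-free limits", {
  n <- 400
  truth <- tibble::tibble(label = rep(0:1, n / 2))
  fr <- withr::with_seed(8, runif(n, 0.1, 0.3))
  null_spec <- default_biomarker_spec(coupling = 0)
  b0 <- generate_biomarkers(truth, null_spec, seed = 1,
                            intratumoral_fraction = fr,
                            peritumoral_fraction = fr)
  expect_lt(abs(cor(fr, b0$cd3_tumor)), 0.15)
  tight_spec <- default_biomarker_spec(coupling = 3000, noise_sd = 1e-9,
                                       cd45_stroma_shift = 0)
  b1 <- generate_biomarkers(truth, tight_spec, seed = 1,
                            intratumoral_fraction = fr,
                            peritumoral_fraction = fr)
  expect_gt(cor(fr, b1$cd3_stroma), 0.999999)
  expect_true(all(b1$cps >= 0 & b1$cps == round(b1$cps)))
  expect_true(all(as.matrix(b1[-1]) >= 0))
  expect_error(default_biomarker_spec(density_base = c(cd45 = -1, cd3 = 1, cd19 = 1)),
               "non-negative")
})

test_that("planted stromal CD45+ shift is detectable with high power", {
  n <- 200
  hits <- vapply(1:100, function(r) {
    withr::with_seed(3000 + r, {
      truth <- tibble::tibble(label = rbinom(n, 1, 0.3))
      fr <- runif(n, 0.1, 0.3)
      b <- generate_biomarkers(truth, default_biomarker_spec(cd45_stroma_shift = 1),
                               seed = 4000 + r,
                               intratumoral_fraction = fr,
                               peritumoral_fraction = fr)
      t.test(b$cd45_stroma[truth$label == 1],
             b$cd45_stroma[truth$label == 0])$p.value < 0.05
    })
  }, logical(1))
  expect_gt(mean(hits), 0.9)
})
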