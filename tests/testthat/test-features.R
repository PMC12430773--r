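test_that("the panel has exactly 107 features with the standard class counts", {
  counts <- vapply(feature_names(), length, integer(1))
  expect_identical(unname(counts[c("Shape", "Firstorder", "GLCM", "GLRLM",
                                   "GLSZM", "NGTDM", "GLDM")]),
                   c(14L, 18L, 24L, 16L, 16L, 5L, 14L))
  expect_identical(length(all_feature_names()), 107L)
  expect_false(anyDuplicated(all_feature_names()) > 0)
})

test_that("constant-intensity region: degenerate first-order and texture values", {
  img <- array(0, c(10, 10, 10)); msk <- array(FALSE, c(10, 10, 10))
  msk[3:8, 3:8, 3:8] <- TRUE; img[msk] <- 42
  fv <- extract_features(img, msk, c(1, 1, 1))
  expect_identical(unname(fv["Firstorder_Variance"]), 0)
  expect_identical(unname(fv["Firstorder_Entropy"]), 0)
  expect_identical(unname(fv["Firstorder_Mean"]), 42)
  expect_identical(unname(fv["GLCM_Contrast"]), 0)
  expect_true(all(is.finite(fv)))
})

test_that("first-order features match direct formulas on enumerable masks", {
  # two-voxel hand case
  img <- array(0, c(4, 4, 4)); msk <- array(FALSE, c(4, 4, 4))
  msk[2, 2, 2] <- TRUE; msk[3, 2, 2] <- TRUE
  img[2, 2, 2] <- 1; img[3, 2, 2] <- 3
  fv <- extract_features(img, msk, c(1, 1, 1), min_voxels = 2)
  expect_identical(unname(fv["Firstorder_Mean"]), 2)
  expect_identical(unname(fv["Firstorder_Variance"]), 1)  # population convention
  # random masks <= 100 voxels against direct formulas
  withr::with_seed(31, {
    for (rep in 1:3) {
      img <- array(rnorm(12^3, 50, 10), c(12, 12, 12))
      msk <- array(FALSE, c(12, 12, 12))
      msk[sample(12^3, sample(30:100, 1))] <- TRUE
      v <- img[msk]
      fv <- extract_features(img, msk, c(1, 1, 1))
      expect_equal(unname(fv["Firstorder_Mean"]), mean(v), tolerance = 1e-9)
      expect_equal(unname(fv["Firstorder_Variance"]), mean((v - mean(v))^2),
                   tolerance = 1e-9)
      expect_equal(unname(fv["Firstorder_Energy"]), sum(v^2), tolerance = 1e-9)
      expect_equal(unname(fv["Firstorder_RootMeanSquared"]),
                   sqrt(mean(v^2)), tolerance = 1e-9)
      expect_equal(unname(fv["Firstorder_10Percentile"]),
                   quantile(v, 0.1, names = FALSE), tolerance = 1e-9)
      expect_equal(unname(fv["Firstorder_Skewness"]),
                   mean((v - mean(v))^3) / mean((v - mean(v))^2)^1.5,
                   tolerance = 1e-9)
    }
  })
})

test_that("shape features are exact on a hand-computable box", {
  msk <- array(FALSE, c(10, 10, 10)); msk[2:5, 2:7, 2:4] <- TRUE  # 4 x 6 x 3
  img <- array(1, c(10, 10, 10))
  fv <- extract_features(img, msk, c(1, 2, 1))  # anisotropic spacing
  # box of 4x6x3 voxels at (1,2,1) mm: physical edges 4, 12, 3 mm
  expect_identical(unname(fv["Shape_VoxelVolume"]), 4 * 12 * 3)
  expect_identical(unname(fv["Shape_SurfaceArea"]),
                   2 * (4 * 12 + 4 * 3 + 12 * 3))
  # diameters measured between voxel centres
  expect_equal(unname(fv["Shape_Maximum3DDiameter"]),
               sqrt(3^2 + 10^2 + 2^2), tolerance = 1e-12)
  expect_equal(unname(fv["Shape_Maximum2DDiameterSlice"]),
               sqrt(3^2 + 10^2), tolerance = 1e-12)
})

test_that("all 107 features are translation invariant and shape features are
           invariant to monotone intensity transforms", {
  withr::with_seed(41, {
    img <- array(rnorm(18^3, 100, 15), c(18, 18, 18))
    msk <- array(FALSE, c(18, 18, 18))
    msk[4:12, 5:13, 6:12] <- runif(9 * 9 * 7) > 0.3
    f0 <- extract_features(img, msk, c(1, 1, 1))
    sh <- array(0, c(18, 18, 18)); shm <- array(FALSE, c(18, 18, 18))
    sh[3:18, 2:17, 4:18] <- img[1:16, 2:17, 1:15]
    shm[6:14, 5:13, 9:15] <- msk[4:12, 5:13, 6:12]
    f1 <- extract_features(sh, shm, c(1, 1, 1))
    expect_equal(f0, f1, tolerance = 1e-12)
    f2 <- extract_features(3 * img + 11, msk, c(1, 1, 1))
    shape_idx <- grep("^Shape_", names(f0))
    expect_equal(f0[shape_idx], f2[shape_idx], tolerance = 1e-9)
  })
})

test_that("GLCM agrees with an explicit pair-enumeration oracle", {
  withr::with_seed(51, {
    img <- array(runif(5 * 5 * 3), c(5, 5, 3))
    msk <- array(runif(5 * 5 * 3) > 0.25, c(5, 5, 3))
    msk[1, 1, 1] <- TRUE
    gl <- array(NA_integer_, dim(msk))
    gl[msk] <- habitomics:::discretize_intensities(img[msk], 4)
    got <- habitomics:::glcm_features(gl)
    names(got) <- feature_names()$GLCM
    expect_equal(unname(got["Contrast"]), glcm_oracle_contrast(gl),
                 tolerance = 1e-12)
  })
})

test_that("GLRLM run accounting is exact on a crafted line pattern", {
  # single 1x6 line: gray pattern 1 1 2 2 2 1 along x
  img <- array(0, c(6, 3, 3)); msk <- array(FALSE, c(6, 3, 3))
  msk[1:6, 2, 2] <- TRUE
  img[1:6, 2, 2] <- c(0, 0, 10, 10, 10, 0)
  fv <- extract_features(img, msk, c(1, 1, 1), n_bins = 2, min_voxels = 2)
  # along x: runs (1,len2),(2,len3),(1,len1); every other direction: 6 runs of 1
  # RunPercentage averaged over 13 directions: (3/6 + 12 * 6/6) / 13
  expect_equal(unname(fv["GLRLM_RunPercentage"]), (0.5 + 12) / 13,
               tolerance = 1e-12)
  # zone accounting (direction-free): gray 1 zones of sizes 2 and 1, one
  # gray 2 zone of size 3 -> ZonePercentage = 3/6
  expect_equal(unname(fv["GLSZM_ZonePercentage"]), 0.5, tolerance = 1e-12)
  expect_equal(unname(fv["GLSZM_SmallAreaEmphasis"]),
               (1 / 4 + 1 + 1 / 9) / 3, tolerance = 1e-12)
})

test_that("GLDM dependence counts match a hand-worked neighbourhood", {
  # 2x2x1 block of identical gray: each voxel has 3 equal neighbours -> j = 4
  img <- array(0, c(4, 4, 3)); msk <- array(FALSE, c(4, 4, 3))
  msk[2:3, 2:3, 2] <- TRUE; img[msk] <- 5
  fv <- extract_features(img, msk, c(1, 1, 1), min_voxels = 2)
  expect_equal(unname(fv["GLDM_LargeDependenceEmphasis"]), 16, tolerance = 1e-12)
  expect_equal(unname(fv["GLDM_SmallDependenceEmphasis"]), 1 / 16, tolerance = 1e-12)
  expect_equal(unname(fv["GLDM_DependenceVariance"]), 0, tolerance = 1e-12)
})

test_that("tiny and empty subregions yield flagged all-missing vectors", {
  img <- array(1, c(6, 6, 6)); msk <- array(FALSE, c(6, 6, 6))
  msk[2, 2, 2] <- TRUE
  fv <- extract_features(img, msk, c(1, 1, 1))
  expect_true(all(is.na(fv)))
  expect_match(attr(fv, "missing_reason"), "voxels")
  fv0 <- extract_features(img, array(FALSE, c(6, 6, 6)), c(1, 1, 1))
  expect_true(all(is.na(fv0)))
  expect_identical(length(fv0), 107L)
})

test_that("feature table: 1070 columns per sequence, missingness, name round trip", {
  co <- small_cohort()
  pats <- lapply(co$patients[1:2], function(p) {
    list(volumes = p$volumes, label_maps = truth_label_maps(p))
  })
  tbl <- build_feature_table(pats, k = 5, min_voxels = 5)
  radio <- setdiff(names(tbl), "patient_id")
  expect_identical(length(radio), 2L * 5L * 3L * 107L)  # 3210
  parsed <- parse_feature_columns(radio)
  for (s in c("T1", "T2", "T1C")) {
    expect_identical(sum(parsed$sequence == s), 1070L)  # 10 subregions x 107
  }
  expect_false(anyDuplicated(radio) > 0)
  # round trip: every column reconstructs uniquely
  rebuilt <- sprintf("%s_%s_h%d_%s_%s", parsed$region, parsed$sequence,
                     parsed$habitat, parsed$class, parsed$feature)
  expect_identical(rebuilt, radio)

  # a patient lacking a habitat in the ring gets missing cells, not dropped columns
  pats2 <- pats
  lm <- pats2[[1]]$label_maps$peritumoral
  lm[lm == 4] <- 3L
  pats2[[1]]$label_maps$peritumoral <- lm
  tbl2 <- build_feature_table(pats2, k = 5, min_voxels = 5)
  h4 <- grep("^P_.*_h4_", names(tbl2), value = TRUE)
  expect_true(all(is.na(tbl2[1, h4])))
  expect_false(all(is.na(tbl2[2, h4])))
  # labels above k are rejected
  expect_error(build_feature_table(pats, k = 3), "above k")
})
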