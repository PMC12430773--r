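test_that("voxel pooling counts rows, keeps channel order, and maps back", {
  co <- small_cohort()
  pooled <- pool_voxels(co$patients, "intratumoral")
  expect_identical(nrow(pooled),
                   sum(vapply(co$patients, function(p) sum(p$masks$tumor),
                              integer(1))))
  expect_identical(names(pooled), c("patient_id", "voxel", "t1", "t2", "t1c"))
  # provenance: each row points at exactly one voxel with those intensities
  r <- pooled[17, ]
  p <- co$patients[[r$patient_id]]
  expect_identical(p$volumes$t1[r$voxel], r$t1)
  expect_identical(p$volumes$t2[r$voxel], r$t2)
  expect_identical(p$volumes$t1c[r$voxel], r$t1c)
  expect_false(anyDuplicated(pooled[c("patient_id", "voxel")]) > 0)
  # empty region errors with the patient named
  bad <- co$patients[1]
  bad[[1]]$masks$tumor[] <- FALSE
  expect_error(pool_voxels(bad, "intratumoral"), "P001")
})

test_that("k-means closed forms: k = 1 and two separated clouds", {
  withr::with_seed(5, {
    x <- matrix(rnorm(600), 200, 3)
    f1 <- fit_kmeans(x, 1)
    expect_equal(f1$centroids[1, ], colMeans(x), tolerance = 1e-12)
    expect_equal(f1$sse, sum(sweep(x, 2, colMeans(x))^2), tolerance = 1e-9)

    cloud <- rbind(matrix(rnorm(300, 0, 0.2), 100, 3),
                   matrix(rnorm(300, 10, 0.2), 100, 3))
    f2 <- fit_kmeans(cloud, 2, seed = 9)
    truth_means <- rbind(colMeans(cloud[1:100, ]), colMeans(cloud[101:200, ]))
    # brute force over both centroid labelings
    perm_err <- min(
      sum((f2$centroids - truth_means)^2),
      sum((f2$centroids - truth_means[2:1, ])^2)
    )
    expect_lt(perm_err, 1e-9)
    expect_true(all(table(f2$cluster, rep(1:2, each = 100)) %in% c(0, 100)))
    # fixed point: re-assigning to the returned centroids changes nothing
    d <- as.matrix(dist(rbind(f2$centroids, cloud)))[1:2, -(1:2)]
    expect_identical(as.integer(apply(d, 2, which.min)), f2$cluster)
  })
  expect_error(fit_kmeans(matrix(rnorm(9), 3, 3), 4), "exceeds")
})

test_that("elbow rule: maximum second difference with smallest-k ties", {
  expect_identical(select_k_elbow(c(100, 60, 30, 28, 27, 26)), 3L)
  expect_identical(select_k_elbow(c(60, 50, 40, 30, 20, 10)), 2L)  # linear: tie
  expect_error(select_k_elbow(c(5, 4)), "at least 3")
  expect_warning(select_k_elbow(c(100, 50, 75, 20, 10)), "non-increasing")
  expect_identical(select_k_elbow(c(50, 30, 28, 27), k = 3:6), 4L)
})

test_that("SSE is non-increasing in k for best-of-restarts fits", {
  withr::with_seed(77, {
    for (rep in 1:3) {
      x <- matrix(rnorm(900), 300, 3) +
        matrix(rnorm(9, sd = 3), 3, 3)[sample(1:3, 300, TRUE), ]
      sse <- vapply(1:8, function(k) fit_kmeans(x, k, seed = rep)$sse,
                    numeric(1))
      expect_true(all(diff(sse) <= 1e-8))
    }
  })
})

test_that("cohort habitat model: assignment identity, determinism, label order", {
  co <- small_cohort()
  pooled <- pool_voxels(co$patients, "intratumoral")
  m <- fit_habitat_model(pooled, k_range = 1:8, seed = 3)
  expect_s3_class(m, "habitat_model")
  expect_true(all(diff(m$centroids[, "t1c"]) > 0))  # h index ascending in T1C

  p <- co$patients[[1]]
  lm1 <- assign_habitats(p$volumes, p$masks$tumor, m)
  lm2 <- assign_habitats(p$volumes, p$masks$tumor, m)
  expect_identical(lm1, lm2)
  expect_true(all(lm1[!p$masks$tumor] == 0))
  expect_true(all(lm1[p$masks$tumor] %in% seq_len(m$k_selected)))

  # a voxel equal to a de-standardized centroid gets that habitat's label
  vol2 <- p$volumes
  cen_raw <- m$centroids[2, ] * m$channel_sds + m$channel_means
  idx <- which(p$masks$tumor)[1]
  vol2$t1[idx] <- cen_raw[1]; vol2$t2[idx] <- cen_raw[2]; vol2$t1c[idx] <- cen_raw[3]
  expect_identical(assign_habitats(vol2, p$masks$tumor, m)[idx], 2L)

  # empty region: all-zero map with warning
  expect_warning(z <- assign_habitats(p$volumes, array(FALSE, dim(p$masks$tumor)), m),
                 "empty")
  expect_true(all(z == 0))
  expect_error(assign_habitats(p$volumes, p$masks$tumor, list()), "not a fitted")
})

test_that("habitat indices are stable across refits with different seeds", {
  co <- small_cohort()
  pooled <- pool_voxels(co$patients, "intratumoral")
  m1 <- fit_habitat_model(pooled, k_range = 1:8, seed = 3)
  m2 <- fit_habitat_model(pooled, k_range = 1:8, seed = 104729)
  expect_identical(m1$k_selected, m2$k_selected)
  p <- co$patients[[2]]
  expect_identical(assign_habitats(p$volumes, p$masks$tumor, m1),
                   assign_habitats(p$volumes, p$masks$tumor, m2))
})

test_that("habitat model survives a JSON round trip", {
  co <- small_cohort()
  m <- fit_habitat_model(pool_voxels(co$patients, "peritumoral"),
                         k_range = 1:6, seed = 3)
  path <- file.path(withr::local_tempdir(), "model.json")
  write_habitat_model(m, path)
  back <- read_habitat_model(path)
  expect_equal(back$centroids, m$centroids, tolerance = 1e-12, ignore_attr = TRUE)
  expect_identical(back$k_selected, m$k_selected)
  p <- co$patients[[1]]
  expect_identical(assign_habitats(p$volumes, p$masks$ring, back),
                   assign_habitats(p$volumes, p$masks$ring, m))
})
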