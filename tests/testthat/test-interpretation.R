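test_that("linear SHAP reproduces the closed form and additivity identity", {
  model <- list(coefficients = c(a = 2, b = 0, c = -1), intercept = 0.5)
  x <- matrix(c(1.5, 2, 3,
                0.5, -1, 0), 2, 3, byrow = TRUE,
              dimnames = list(NULL, c("a", "b", "c")))
  bg <- matrix(c(0.5, 0, 1), 1, 3, dimnames = list(NULL, c("a", "b", "c")))
  sh <- linear_shap(model, x, bg)
  # beta (x - background mean): 2 * (1.5 - 0.5) = 2
  expect_equal(unname(sh$attributions[1, "a"]), 2, tolerance = 1e-12)
  # zero coefficient -> zero attribution everywhere
  expect_true(all(sh$attributions[, "b"] == 0))
  expect_equal(sh$base_value + rowSums(sh$attributions), sh$score,
               tolerance = 1e-12)
  # permuting a zero-coefficient feature's column changes no attribution
  x2 <- x; x2[, "b"] <- rev(x2[, "b"])
  sh2 <- linear_shap(model, x2, bg)
  expect_identical(sh$attributions, sh2$attributions)
})

test_that("nonlinear classifiers are rejected by the closed-form explainer", {
  withr::with_seed(7, {
    x <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
    y <- rbinom(20, 1, 0.5); y[1:3] <- 1; y[4:6] <- 0
    rf <- habitomics:::fit_classifier(x, y, "rf", seed = 1)
    expect_error(linear_shap(rf, x, x), "model-agnostic")
  })
})

test_that("per-fold ranking pools the documented counts with stable ties", {
  mk <- function(imp_named) {
    structure(list(importance = tibble::tibble(
      feature = names(imp_named), importance = unname(imp_named)
    ) |> dplyr::arrange(dplyr::desc(importance), feature)),
    class = "shap_explanation")
  }
  same <- lapply(1:5, function(i) mk(c(a = 3, b = 2, c = 1, d = 0.1)))
  expect_identical(nrow(rank_and_pool(same, 3)), 3L)
  disjoint <- lapply(1:5, function(i) {
    v <- c(3, 2, 1); names(v) <- paste0("f", (i - 1) * 3 + 1:3)
    mk(v)
  })
  expect_identical(nrow(rank_and_pool(disjoint, 3)), 15L)
  # tie at rank 3 decided by name, stable across calls
  tied <- list(mk(c(zz = 3, m = 2, aa = 1, bb = 1)))
  p1 <- rank_and_pool(tied, 3)
  expect_identical(p1$feature, c("zz", "m", "aa"))
  expect_error(rank_and_pool(tied, 0), "top_m")
})

test_that("CPS association: null identity, power case, boundary membership", {
  v <- rep(c(1, 2, 3, 4), 8)
  cps <- rep(c(20, 20, 5, 5), 8)
  # both groups carry the same value distribution -> t is exactly 0
  same <- cps_association(rep(c(1, 2, 1, 2), 8), rep(c(20, 20, 5, 5), 8))
  expect_equal(same$statistic, 0, tolerance = 1e-12)

  withr::with_seed(11, {
    x <- c(rnorm(16, 0, 0.1), rnorm(16, 1, 0.1))
    scores <- c(rep(5, 16), rep(20, 16))
    r <- cps_association(x, scores)
    expect_lt(r$p_value, 0.05)
    expect_true(r$significant)
  })

  # a score of exactly 15 belongs to the high group
  b <- cps_association(c(1, 2, 3, 4), c(15, 15, 3, 3))
  expect_identical(b$n_high, 2L)
  expect_error(cps_association(v, rep(20, 32)), "empty")
  expect_error(cps_association(v, rep(3, 32)), "empty")
})

test_that("biomarker correlation: exact limits, errors, small-n power", {
  x <- c(1, 2, 3, 5, 8)
  up <- biomarker_correlation(x, x)
  expect_equal(up$r, 1, tolerance = 1e-12)
  expect_true(up$strong)
  dn <- biomarker_correlation(x, -x)
  expect_equal(dn$r, -1, tolerance = 1e-12)
  expect_true(dn$strong)
  expect_error(biomarker_correlation(x, rep(2, 5)), "variance")
  expect_error(biomarker_correlation(1:2, 2:1), "at least 3")

  # planted r = 0.9 at n = 6: |r| > 0.75 in the majority of draws
  withr::with_seed(13, {
    hits <- replicate(1000, {
      z <- rnorm(6)
      y <- 0.9 * z + sqrt(1 - 0.81) * rnorm(6)
      abs(cor(z, y)) > 0.75
    })
    expect_gt(mean(hits), 0.5)
  })
})
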