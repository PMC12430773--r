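test_that("imputation: identity, nearest-duplicate fill, clinical median, errors", {
  tbl <- tibble::tibble(a = c(1, 2, 3), b = c(4, 5, 6))
  expect_identical(impute_missing(tbl), tbl)

  # one missing cell, k = 1, an exact duplicate row exists
  t2 <- tibble::tibble(a = c(1, 1, 8), b = c(2, 2, 9), c = c(5, NA, 7))
  out <- impute_missing(t2, k_neighbors = 1)
  expect_identical(out$c[2], 5)

  # clinical gap: training-column median
  t3 <- tibble::tibble(a = rnorm(5), clin = c(1, 2, NA, 4, 10))
  out3 <- impute_missing(t3, clinical_cols = "clin")
  expect_identical(out3$clin[3], median(c(1, 2, 4, 10)))

  expect_error(impute_missing(tibble::tibble(a = 1:3, b = rep(NA_real_, 3))),
               "\\bb\\b")
})

test_that("Pearson filter: duplicates, affine copies, independent survivors", {
  withr::with_seed(61, {
    x <- tibble::tibble(f_a = rnorm(100))
    x$f_dup <- x$f_a
    x$f_aff <- 3 * x$f_a + 7
    x$f_ind <- rnorm(100)
    kept <- pearson_redundancy_filter(x, 0.95)
    expect_identical(sum(c("f_a", "f_dup", "f_aff") %in% kept), 1L)
    expect_true("f_ind" %in% kept)

    g <- as.data.frame(matrix(rnorm(500 * 50), 500, 50))
    names(g) <- sprintf("g%02d", 1:50)
    expect_identical(sort(pearson_redundancy_filter(g, 0.95)), sort(names(g)))

    cst <- tibble::tibble(a = rnorm(30), b = rep(1, 30))
    expect_warning(kept2 <- pearson_redundancy_filter(cst, 0.95), "constant")
    expect_identical(kept2, "a")
  })
})

test_that("Pearson filter victim choice is deterministic with the stated tie rule", {
  withr::with_seed(62, {
    base <- rnorm(200)
    x <- tibble::tibble(aaa = base + rnorm(200, 0, 0.01),
                        zzz = base + rnorm(200, 0, 0.01))
    k1 <- pearson_redundancy_filter(x, 0.95)
    k2 <- pearson_redundancy_filter(x[c("zzz", "aaa")], 0.95)
    expect_identical(sort(k1), sort(k2))  # order of columns is irrelevant
    expect_identical(length(k1), 1L)
  })
})

test_that("LASSO selection finds planted signal, stays small under the null,
           and is deterministic", {
  withr::with_seed(71, {
    hits <- logical(100); null_sizes <- integer(100)
    for (r in 1:100) {
      x <- matrix(rnorm(300 * 50), 300, 50,
                  dimnames = list(NULL, sprintf("f%02d", 1:50)))
      y <- rbinom(300, 1, plogis(2 * x[, 1]))
      hits[r] <- "f01" %in% names(lasso_select(x, y, seed = r)$selected)
      y0 <- rbinom(300, 1, 0.5)
      null_sizes[r] <- length(lasso_select(x, y0, seed = r)$selected)
    }
    expect_gte(mean(hits), 0.95)
    expect_lte(median(null_sizes), 2)
  })
  x <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, letters[1:4]))
  y <- rbinom(50, 1, 0.5)
  expect_identical(lasso_select(x, y, seed = 5)$selected,
                   lasso_select(x, y, seed = 5)$selected)
  expect_error(lasso_select(x, rep(1, 50)), "single class")
})

test_that("confusion metrics match closed forms and precision equals PPV", {
  m <- confusion_metrics(30, 10, 5, 55)
  expect_equal(m$precision, 0.75, tolerance = 1e-12)
  expect_equal(m$recall, 30 / 35, tolerance = 1e-12)
  expect_equal(m$f1, 0.8, tolerance = 1e-12)
  expect_equal(m$npv, 55 / 60, tolerance = 1e-12)
  expect_equal(m$accuracy, 85 / 100, tolerance = 1e-12)
  expect_identical(m$ppv, m$precision)
})

test_that("stratified folds keep class balance within one patient", {
  withr::with_seed(81, {
    for (rep in 1:5) {
      n <- sample(20:80, 1)
      y <- rbinom(n, 1, runif(1, 0.2, 0.5))
      if (sum(y) < 5) y[sample(n, 5)] <- 1
      nf <- sample(3:5, 1)
      f <- stratified_folds(y, nf, seed = rep)
      pos <- table(factor(f, levels = 1:nf), y)[, "1"]
      expect_lte(max(pos) - min(pos), 1)
      tot <- table(factor(f, levels = 1:nf))
      expect_lte(max(tot) - min(tot), 2)
    }
  })
  expect_error(stratified_folds(c(1, 0, 0, 0, 0, 0), 3, seed = 1),
               "fewer")
})

test_that("cross-validation: separable data gives AUC 1, permuted labels ~0.5", {
  withr::with_seed(91, {
    x <- rbind(matrix(rnorm(150, 0, 0.3), 50, 3),
               matrix(rnorm(150, 8, 0.3), 50, 3))
    colnames(x) <- c("u", "v", "w")
    y <- rep(0:1, each = 50)
    cv <- crossvalidate(tibble::as_tibble(x), y, classifier = "lr",
                        n_folds = 5, seed = 2)
    expect_equal(cv$summary$mean[cv$summary$metric == "auc"], 1,
                 tolerance = 1e-12)
    expect_identical(cv$summary$mean[cv$summary$metric == "precision"],
                     cv$summary$mean[cv$summary$metric == "ppv"])

    x2 <- matrix(rnorm(60 * 8), 60, 8,
                 dimnames = list(NULL, sprintf("n%d", 1:8)))
    aucs <- vapply(1:20, function(s) {
      yp <- sample(rep(0:1, each = 30))
      cvp <- crossvalidate(tibble::as_tibble(x2), yp, classifier = "lr",
                           n_folds = 5, seed = s)
      cvp$summary$mean[cvp$summary$metric == "auc"]
    }, numeric(1))
    expect_gt(mean(aucs), 0.4)
    expect_lt(mean(aucs), 0.6)
  })
})

test_that("every classifier runs through the per-fold pipeline deterministically", {
  withr::with_seed(95, {
    x <- matrix(rnorm(60 * 6), 60, 6,
                dimnames = list(NULL, sprintf("c%d", 1:6)))
    y <- as.integer(x[, 1] + rnorm(60, 0, 0.8) > 0)
    for (clf in c("lr", "svm", "knn", "dt", "rf")) {
      a <- crossvalidate(tibble::as_tibble(x), y, classifier = clf,
                         n_folds = 3, seed = 7)
      b <- crossvalidate(tibble::as_tibble(x), y, classifier = clf,
                         n_folds = 3, seed = 7)
      expect_identical(a$folds, b$folds)
      expect_true(all(a$folds$auc >= 0 & a$folds$auc <= 1))
    }
  })
})

test_that("no statistic fitted on a training fold depends on held-out rows", {
  withr::with_seed(101, {
    x <- matrix(rnorm(40 * 10), 40, 10,
                dimnames = list(NULL, sprintf("f%d", 1:10)))
    x[3, 4] <- NA  # exercise the imputer too
    y <- as.integer(x[, 1] + rnorm(40) > 0)
    if (length(unique(y)) < 2) y[1:5] <- 1 - y[1]
    cv1 <- crossvalidate(tibble::as_tibble(x), y, classifier = "lr",
                         n_folds = 4, seed = 9)
    fold <- stratified_folds(y, 4, seed = 9)
    for (f in 1:4) {
      xc <- x
      xc[fold == f, ] <- xc[fold == f, ] * 100 + 3  # corrupt held-out rows
      cv2 <- crossvalidate(tibble::as_tibble(xc), y, classifier = "lr",
                           n_folds = 4, seed = 9)
      s1 <- cv1$fits[[f]]$selection
      s2 <- cv2$fits[[f]]$selection
      expect_identical(s1$retained, s2$retained)
      expect_identical(s1$lasso$selected, s2$lasso$selected)
      expect_identical(s1$lasso$zscore, s2$lasso$zscore)
      expect_identical(s1$imputer$medians, s2$imputer$medians)
      expect_identical(cv1$fits[[f]]$classifier$fit,
                       cv2$fits[[f]]$classifier$fit)
    }
  })
})

test_that("model suite scopes follow the naming scheme and nest correctly", {
  cols <- as.vector(outer(
    c("I", "P"),
    as.vector(outer(c("T1", "T2", "T1C"), 1:5,
                    function(s, h) sprintf("%s_h%d_Firstorder_Mean", s, h))),
    paste, sep = "_"
  ))
  scopes <- model_suite_scopes(cols, clinical_candidates = c("agr"))
  expect_identical(length(scopes[["Intra-Fusion"]]), 15L)
  expect_identical(length(scopes[["T1C-Intra"]]), 5L)
  expect_false(any(scopes[["T1-Intra"]] %in% scopes[["T1C-Intra"]]))
  expect_true(all(union(scopes[["Intra-Fusion"]], scopes[["Peri-Fusion"]])
                  %in% scopes[["Decision"]]))
  expect_true("agr" %in% scopes[["Decision"]])
  expect_error(model_suite_scopes(cols[1:5]), "zero columns")
})

test_that("a full-feature table yields the published candidate-pool sizes", {
  co <- small_cohort()
  pats <- lapply(co$patients, function(p) {
    list(volumes = p$volumes, label_maps = truth_label_maps(p))
  })
  tbl <- cached("small_feature_table",
                build_feature_table(pats, k = 5, min_voxels = 5))
  radio <- grep("^[IP]_", names(tbl), value = TRUE)
  scopes <- model_suite_scopes(radio)
  expect_identical(length(scopes[["Intra-Fusion"]]), 5L * 107L * 3L)  # 1605
  expect_identical(length(scopes[["Peri-Fusion"]]), 1605L)
  expect_identical(length(scopes[["Decision"]]), 3210L)
})
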