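#' K-nearest-neighbour / median imputation
#'
#' Radiomic gaps are filled by averaging the `k_neighbors` nearest rows (NaN-
#' aware Euclidean distance, scaled by the fraction of jointly observed
#' columns) that have the cell observed; clinical gaps are filled with the
#' column median. When used inside cross-validation the neighbour pool and
#' medians come from the training fold only (see [crossvalidate()]); the
#' exported function fits and applies on the same table.
#'
#' @param table Data frame / tibble of numeric feature columns (a
#'   `patient_id` column is carried through untouched).
#' @param k_neighbors Number of neighbours for radiomic cells (default 5).
#' @param clinical_cols Character vector naming columns imputed by median
#'   instead of KNN.
#' @return The table with no missing cells.
#' @export
impute_missing <- function(table, k_neighbors = 5, clinical_cols = NULL) {
  imp <- fit_imputer(table, k_neighbors = k_neighbors,
                     clinical_cols = clinical_cols)
  apply_imputer(imp, table)
}

fit_imputer <- function(train, k_neighbors = 5, clinical_cols = NULL) {
  id <- intersect("patient_id", names(train))
  feat <- setdiff(names(train), id)
  all_missing <- feat[vapply(train[feat], function(v) all(is.na(v)), logical(1))]
  if (length(all_missing)) {
    abort(sprintf("column(s) entirely missing: %s",
                  paste(all_missing, collapse = ", ")))
  }
  clinical_cols <- intersect(clinical_cols %||% character(0), feat)
  radiomic <- setdiff(feat, clinical_cols)
  list(
    k = k_neighbors,
    clinical_cols = clinical_cols,
    medians = vapply(train[clinical_cols], median, numeric(1), na.rm = TRUE),
    radiomic = radiomic,
    train_mat = as.matrix(train[radiomic])
  )
}

apply_imputer <- function(imp, table) {
  out <- table
  for (cc in imp$clinical_cols) {
    v <- out[[cc]]
    v[is.na(v)] <- imp$medians[[cc]]
    out[[cc]] <- v
  }
  m <- as.matrix(out[imp$radiomic])
  if (anyNA(m)) {
    tm <- imp$train_mat
    p <- ncol(m)
    need <- which(rowSums(is.na(m)) > 0)
    for (r in need) {
      row <- m[r, ]
      obs <- !is.na(row)
      # NaN-aware Euclidean distance to every training row
      diffs <- sweep(tm[, obs, drop = FALSE], 2, row[obs])
      shared <- rowSums(!is.na(diffs))
      d2 <- rowSums(diffs^2, na.rm = TRUE) * p / pmax(shared, 1)
      d2[shared == 0] <- Inf
      for (j in which(!obs)) {
        donors <- which(!is.na(tm[, j]))
        donors <- donors[order(d2[donors])]
        use <- utils::head(donors, imp$k)
        m[r, j] <- mean(tm[use, j])
      }
    }
    out[imp$radiomic] <- as.data.frame(m)
  }
  out
}

#' Pearson redundancy filter
#'
#' Repeatedly removes one feature of every pair whose absolute Pearson
#' correlation exceeds the threshold. Within an offending pair the victim is
#' the feature with the larger mean absolute correlation to all other
#' currently retained features (ties: the lexicographically later name), so
#' the result is deterministic. Constant columns (undefined correlation) are
#' removed first with a warning.
#'
#' @param table Numeric data frame / matrix (no missing values).
#' @param threshold Absolute-correlation threshold (default 0.95, strict:
#'   pairs with `|r|` exceeding it are broken up).
#' @return Character vector of retained column names.
#' @export
pearson_redundancy_filter <- function(table, threshold = 0.95) {
  m <- as.matrix(as.data.frame(table)[, setdiff(colnames(as.data.frame(table)), "patient_id"), drop = FALSE])
  sds <- apply(m, 2, sd)
  if (any(sds == 0 | is.na(sds))) {
    bad <- colnames(m)[sds == 0 | is.na(sds)]
    warn(sprintf("removing %d constant column(s) before correlation filtering.",
                 length(bad)))
    m <- m[, !(colnames(m) %in% bad), drop = FALSE]
  }
  if (ncol(m) < 2) return(colnames(m))
  ac <- abs(stats::cor(m))
  diag(ac) <- 0
  alive <- rep(TRUE, ncol(ac))
  names(alive) <- colnames(ac)
  pairs <- which(upper.tri(ac) & ac > threshold, arr.ind = TRUE)
  if (nrow(pairs)) {
    ord <- order(ac[pairs], decreasing = TRUE)
    pairs <- pairs[ord, , drop = FALSE]
    for (pi in seq_len(nrow(pairs))) {
      a <- pairs[pi, 1]; b <- pairs[pi, 2]
      if (!alive[a] || !alive[b]) next
      mean_a <- mean(ac[a, alive])
      mean_b <- mean(ac[b, alive])
      victim <- if (mean_a > mean_b) a
        else if (mean_b > mean_a) b
        else if (colnames(ac)[a] > colnames(ac)[b]) a else b
      alive[victim] <- FALSE
    }
  }
  colnames(ac)[alive]
}

#' Cross-validated LASSO feature selection
#'
#' Z-scores the features (training statistics), then runs a 10-fold
#' cross-validated LASSO over glmnet's log-spaced penalty grid and keeps the
#' features with non-zero coefficients at the loss-minimizing penalty. An
#' empty selection is allowed and flagged.
#'
#' @param x Numeric matrix / data frame of features.
#' @param labels Binary outcome (0/1) with both classes present.
#' @param n_folds Cross-validation folds for the penalty search (default 10,
#'   capped at the sample size).
#' @param seed RNG seed (fold assignment).
#' @return A `selection_result` list: `zscore` (means/sds), `lasso_alpha`
#'   (chosen penalty), `selected` (named coefficient vector), `empty` flag.
#' @export
lasso_select <- function(x, labels, n_folds = 10, seed = 1) {
  x <- as.matrix(as.data.frame(x)[, setdiff(colnames(as.data.frame(x)), "patient_id"), drop = FALSE])
  y <- as.numeric(labels)
  if (length(unique(y)) < 2) abort("labels contain a single class.")
  sc <- fit_zscore(x)
  xs <- apply_zscore(sc, x)
  nf <- max(3L, min(n_folds, nrow(xs)))
  xfit <- if (ncol(xs) >= 2) xs else cbind(xs, `.pad.` = 0)
  min_class <- min(table(y))
  if (min_class >= 2) {
    # stratified inner folds: every class lands in >= 2 folds, so no
    # training complement is single-class
    foldid <- integer(length(y))
    with_seed(derive_seed(seed, "lassocv"), {
      for (cl in unique(y)) {
        idx <- sample(which(y == cl))
        foldid[idx] <- rep_len(seq_len(nf), length(idx))
      }
    })
    cv <- withCallingHandlers(
      glmnet::cv.glmnet(xfit, y, family = "gaussian", alpha = 1,
                        foldid = foldid, standardize = FALSE),
      warning = function(w) {
        # tiny inner folds trigger an informational grouping warning
        if (grepl("grouped=FALSE", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      }
    )
    lambda <- cv$lambda.min
    fit <- cv$glmnet.fit
  } else {
    # a class with a single member cannot be cross-validated; fall back to
    # BIC along the glmnet path
    fit <- glmnet::glmnet(xfit, y, family = "gaussian", alpha = 1,
                          standardize = FALSE)
    pred <- stats::predict(fit, xfit)
    n <- length(y)
    rss <- colSums((pred - y)^2)
    bic <- n * log(pmax(rss, 1e-12) / n) + fit$df * log(n)
    lambda <- fit$lambda[which.min(bic)]
  }
  cf <- as.matrix(stats::coef(fit, s = lambda, exact = FALSE))[-1, , drop = FALSE]
  nz <- cf[, 1][cf[, 1] != 0]
  nz <- nz[names(nz) != ".pad."]
  structure(
    list(zscore = sc, lasso_alpha = lambda,
         selected = nz, empty = length(nz) == 0),
    class = "selection_result"
  )
}

fit_zscore <- function(x) {
  mu <- colMeans(x)
  sdev <- apply(x, 2, sd)
  sdev[sdev == 0 | is.na(sdev)] <- 1
  list(mean = mu, sd = sdev)
}

apply_zscore <- function(sc, x) {
  sweep(sweep(as.matrix(x), 2, sc$mean), 2, sc$sd, "/")
}

# ---- classifiers ------------------------------------------------------------

# The five classifiers behind the model suite. All return probabilities of
# the positive class; the logistic model is ridge-penalized (lambda = 1/n,
# the analogue of C = 1) and exposes its coefficients for SHAP.
fit_classifier <- function(x, y, classifier = c("lr", "svm", "knn", "dt", "rf"),
                           seed = 1) {
  classifier <- match.arg(classifier)
  x <- as.matrix(x)
  yf <- factor(y, levels = c(0, 1))
  fit <- switch(classifier,
    lr = fit_ridge_logistic(x, as.numeric(y)),
    svm = with_seed(derive_seed(seed, "svm"),
                    e1071::svm(x, yf, kernel = "radial", scale = FALSE)),
    knn = list(train = x, cl = yf, k = min(5L, nrow(x))),
    dt = {
      df <- data.frame(.y = yf, x, check.names = FALSE)
      with_seed(derive_seed(seed, "dt"),
                rpart::rpart(.y ~ ., data = df, method = "class"))
    },
    rf = with_seed(derive_seed(seed, "rf"),
                   randomForest::randomForest(x, yf, ntree = 100))
  )
  structure(list(classifier = classifier, fit = fit, seed = seed,
                 features = colnames(x)),
            class = "habitat_classifier")
}

predict_classifier <- function(model, x) {
  x <- as.matrix(x)
  switch(model$classifier,
    lr = stats::plogis(model$fit$intercept +
                         as.numeric(x[, names(model$fit$coefficients),
                                      drop = FALSE] %*% model$fit$coefficients)),
    svm = {
      dv <- attr(stats::predict(model$fit, x, decision.values = TRUE),
                 "decision.values")
      # orient the decision value so larger means the positive class
      flip <- if (grepl("^0/1", colnames(dv)[1])) -1 else 1
      stats::plogis(flip * as.numeric(dv))
    },
    knn = with_seed(derive_seed(model$seed, "knn-pred"), {
      pr <- class::knn(model$fit$train, x, model$fit$cl, k = model$fit$k,
                       prob = TRUE)
      win <- attr(pr, "prob")
      ifelse(pr == "1", win, 1 - win)
    }),
    dt = {
      df <- data.frame(x, check.names = FALSE)
      as.numeric(stats::predict(model$fit, newdata = df, type = "prob")[, "1"])
    },
    rf = as.numeric(stats::predict(model$fit, x, type = "prob")[, "1"])
  )
}

# L2-penalized logistic regression by Newton iterations, minimizing
# -loglik + 1/(2C) ||beta||^2 (intercept unpenalized; C = 1 default).
# Deterministic and well-defined even when a training class has one member.
fit_ridge_logistic <- function(x, y, C = 1, max_iter = 100, tol = 1e-10) {
  x <- as.matrix(x)
  X <- cbind(`(Intercept)` = 1, x)
  p <- ncol(X)
  lambda <- c(0, rep(1 / C, p - 1))
  beta <- numeric(p)
  for (it in seq_len(max_iter)) {
    eta <- as.numeric(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    g <- as.numeric(crossprod(X, mu - y)) + lambda * beta
    H <- crossprod(X * w, X) + diag(lambda + 1e-12, p)
    step <- solve(H, g)
    beta <- beta - step
    if (max(abs(step)) < tol) break
  }
  list(intercept = beta[1],
       coefficients = stats::setNames(beta[-1], colnames(x)))
}

# ---- metrics ----------------------------------------------------------------

#' Classification metrics from a confusion matrix
#'
#' @param tp,fp,fn,tn Confusion-matrix counts at the chosen threshold.
#' @return A one-row tibble with accuracy, recall, precision, f1, ppv, npv
#'   (ppv is precision by definition; both are reported because standard
#'   performance tables print both).
#' @export
confusion_metrics <- function(tp, fp, fn, tn) {
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  tibble(
    accuracy = (tp + tn) / (tp + fp + fn + tn),
    recall = recall,
    precision = precision,
    f1 = f1,
    ppv = precision,
    npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_
  )
}

roc_auc <- function(y, prob) {
  if (length(unique(y)) < 2) return(NA_real_)
  as.numeric(pROC::auc(pROC::roc(response = y, predictor = prob,
                                 levels = c(0, 1), direction = "<",
                                 quiet = TRUE)))
}

#' Stratified fold assignment
#'
#' Assigns fold ids so each fold's class counts differ from perfect
#' proportionality by at most one patient per class.
#'
#' @param labels Binary labels.
#' @param n_folds Number of folds.
#' @param seed RNG seed.
#' @return Integer vector of fold ids in `1..n_folds`.
#' @export
stratified_folds <- function(labels, n_folds, seed = 1) {
  fold <- integer(length(labels))
  with_seed(derive_seed(seed, "folds"), {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      idx <- sample(idx)
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  counts <- table(factor(fold, levels = seq_len(n_folds)), labels)
  if (any(counts == 0)) {
    abort(sprintf("a fold would contain a single class; use fewer than %d folds.",
                  n_folds))
  }
  fold
}

#' Cross-validated habitat-model evaluation
#'
#' Stratified k-fold cross-validation of the full per-fold pipeline:
#' imputation -> Z-score -> Pearson redundancy filter -> cross-validated
#' LASSO selection -> classifier, with every statistic fitted on the training
#' fold only and applied unchanged to the held-out fold (no leakage). With
#' `selection = "pooled"` the selection stages are instead fitted once on all
#' data before the folds are cut — the variant many radiomics studies
#' describe — and only the classifier is refitted per fold; the leakage-safe
#' `"fold"` variant is the default.
#'
#' @param table Feature table (numeric columns; `patient_id` carried through).
#' @param labels Binary outcome, one per row.
#' @param classifier One of `"lr"`, `"svm"`, `"knn"`, `"dt"`, `"rf"`.
#' @param n_folds Number of stratified folds (default 5).
#' @param seed RNG seed governing folds and stochastic classifiers.
#' @param selection `"fold"` (selection inside each fold) or `"pooled"`.
#' @param k_neighbors KNN-imputer neighbours.
#' @param clinical_cols Columns imputed by median rather than KNN.
#' @param pearson_threshold Redundancy-filter threshold.
#' @param lasso_folds Folds for the LASSO penalty search.
#' @param threshold Probability threshold for confusion-matrix metrics.
#' @return A `habitat_cv` object: per-fold metrics (`folds`), their mean/sd
#'   (`summary`), pooled held-out `predictions`, per-fold ROC points,
#'   calibration bins, confusion matrices, and the per-fold fitted pipeline
#'   (`fits`) for interpretation.
#' @export
crossvalidate <- function(table, labels, classifier = "lr", n_folds = 5,
                          seed = 1, selection = c("fold", "pooled"),
                          k_neighbors = 5, clinical_cols = NULL,
                          pearson_threshold = 0.95, lasso_folds = 10,
                          threshold = 0.5) {
  selection <- match.arg(selection)
  df <- as_tibble(table)
  id <- if ("patient_id" %in% names(df)) df$patient_id else sprintf("row%d", seq_len(nrow(df)))
  df <- df[setdiff(names(df), "patient_id")]
  y <- as.integer(labels)
  stopifnot(length(y) == nrow(df))
  fold <- stratified_folds(y, n_folds, seed)

  pooled_sel <- NULL
  if (selection == "pooled") {
    pooled_sel <- fit_selection(df, y, k_neighbors, clinical_cols,
                                pearson_threshold, lasso_folds, seed)
  }

  folds <- list()
  preds <- list()
  fits <- list()
  rocs <- list()
  confusions <- list()
  for (f in seq_len(n_folds)) {
    tr <- fold != f; te <- fold == f
    sel <- pooled_sel %||% fit_selection(df[tr, ], y[tr], k_neighbors,
                                         clinical_cols, pearson_threshold,
                                         lasso_folds, derive_seed(seed, paste0("fold", f)))
    xtr <- apply_selection(sel, df[tr, ])
    xte <- apply_selection(sel, df[te, ])
    if (ncol(xtr) == 0) {
      # empty LASSO selection: constant classifier at the training prevalence
      p_tr <- mean(y[tr])
      prob <- rep(p_tr, sum(te))
      clf <- NULL
    } else {
      clf <- fit_classifier(xtr, y[tr], classifier,
                            seed = derive_seed(seed, paste0("clf", f)))
      prob <- predict_classifier(clf, xte)
    }
    pred <- as.integer(prob >= threshold)
    tp <- sum(pred == 1 & y[te] == 1); fp <- sum(pred == 1 & y[te] == 0)
    fn <- sum(pred == 0 & y[te] == 1); tn <- sum(pred == 0 & y[te] == 0)
    folds[[f]] <- dplyr::bind_cols(
      tibble(fold = f, auc = roc_auc(y[te], prob)),
      confusion_metrics(tp, fp, fn, tn)
    )
    confusions[[f]] <- c(tp = tp, fp = fp, fn = fn, tn = tn)
    preds[[f]] <- tibble(fold = f, patient_id = id[te], label = y[te],
                         prob = prob)
    rocs[[f]] <- roc_points(y[te], prob) |> dplyr::mutate(fold = f, .before = 1)
    fits[[f]] <- list(selection = sel, classifier = clf,
                      train_ids = id[tr], test_ids = id[te],
                      x_train = xtr, x_test = xte)
  }
  folds <- dplyr::bind_rows(folds)
  metric_cols <- setdiff(names(folds), "fold")
  summary <- tibble(
    metric = metric_cols,
    mean = unname(vapply(folds[metric_cols], mean, numeric(1), na.rm = TRUE)),
    sd = unname(vapply(folds[metric_cols], sd, numeric(1), na.rm = TRUE))
  )
  preds <- dplyr::bind_rows(preds)
  structure(
    list(classifier = classifier, n_folds = n_folds, seed = seed,
         selection = selection, threshold = threshold, ids = id, data = df,
         folds = folds, summary = summary, predictions = preds,
         roc = dplyr::bind_rows(rocs),
         calibration = calibration_bins(preds$prob, preds$label, 10),
         confusion = confusions, fits = fits),
    class = "habitat_cv"
  )
}

#' @export
print.habitat_cv <- function(x, ...) {
  m <- x$summary
  cat(sprintf("<habitat_cv> %s, %d-fold (selection: %s)\n", x$classifier,
              x$n_folds, x$selection))
  cat(sprintf("  mean AUC %.3f (sd %.3f), accuracy %.3f\n",
              m$mean[m$metric == "auc"], m$sd[m$metric == "auc"],
              m$mean[m$metric == "accuracy"]))
  invisible(x)
}

# one fitted selection pipeline: imputer -> zscore -> pearson -> lasso
fit_selection <- function(train, y, k_neighbors, clinical_cols,
                          pearson_threshold, lasso_folds, seed) {
  imp <- fit_imputer(train, k_neighbors = k_neighbors,
                     clinical_cols = clinical_cols)
  tr_imp <- apply_imputer(imp, train)
  retained <- suppressWarnings(
    pearson_redundancy_filter(tr_imp, threshold = pearson_threshold)
  )
  sel <- lasso_select(tr_imp[retained], y, n_folds = lasso_folds, seed = seed)
  list(imputer = imp, retained = retained, lasso = sel)
}

apply_selection <- function(sel, newdata) {
  nd <- apply_imputer(sel$imputer, newdata)
  keep <- names(sel$lasso$selected)
  xs <- apply_zscore(sel$lasso$zscore, as.matrix(nd[sel$retained]))
  xs[, keep, drop = FALSE]
}

roc_points <- function(y, prob) {
  th <- sort(unique(c(-Inf, prob, Inf)), decreasing = TRUE)
  tibble(
    threshold = th,
    tpr = vapply(th, function(t) mean(prob[y == 1] >= t), numeric(1)),
    fpr = vapply(th, function(t) mean(prob[y == 0] >= t), numeric(1))
  )
}

calibration_bins <- function(prob, y, n_bins = 10) {
  qs <- unique(quantile(prob, probs = seq(0, 1, length.out = n_bins + 1),
                        names = FALSE))
  if (length(qs) < 2) qs <- c(qs - 1e-9, qs + 1e-9)
  binv <- cut(prob, breaks = qs, include.lowest = TRUE)
  tibble(
    bin = levels(binv),
    mean_predicted = as.numeric(tapply(prob, binv, mean)),
    observed_rate = as.numeric(tapply(y, binv, mean)),
    n = as.integer(table(binv))
  )
}

# ---- model suite ------------------------------------------------------------

#' Column scopes of the standard model suite
#'
#' Per-sequence intratumoral habitat-imaging (HI) models, the intratumoral
#' fusion model (all intratumoral habitat columns), their peritumoral
#' counterparts, and the decision model (all intratumoral + peritumoral
#' habitat columns + clinical candidates).
#'
#' @param columns All radiomic column names.
#' @param clinical_candidates Clinical column names entering the decision
#'   model.
#' @return Named list of character vectors.
#' @export
model_suite_scopes <- function(columns, clinical_candidates = character(0)) {
  pick <- function(prefix) columns[startsWith(columns, prefix)]
  scopes <- list(
    "T1-Intra" = pick("I_T1_"),
    "T1C-Intra" = pick("I_T1C_"),
    "T2-Intra" = pick("I_T2_"),
    "Intra-Fusion" = pick("I_"),
    "T1-Peri" = pick("P_T1_"),
    "T1C-Peri" = pick("P_T1C_"),
    "T2-Peri" = pick("P_T2_"),
    "Peri-Fusion" = pick("P_"),
    "Decision" = c(pick("I_"), pick("P_"), clinical_candidates)
  )
  empty <- names(scopes)[vapply(scopes, length, integer(1)) == 0]
  if (length(empty)) {
    abort(sprintf("model scope(s) with zero columns: %s",
                  paste(empty, collapse = ", ")))
  }
  scopes
}

#' Fit and evaluate the full model suite
#'
#' Runs [crossvalidate()] with the identical per-fold pipeline over every
#' scope of [model_suite_scopes()].
#'
#' @param feature_table Cohort feature table (radiomic columns named by the
#'   `{P|I}_{seq}_h{n}_{Class}_{Feature}` scheme, plus clinical columns).
#' @param labels Binary outcome per row.
#' @param clinical_candidates Clinical columns offered to the decision model.
#' @param models Subset of suite model ids to run (default: all nine).
#' @param ... Passed to [crossvalidate()].
#' @return A `habitat_suite`: named list of `habitat_cv` objects with a
#'   `report` tibble attached (one row per model x metric layout mirroring
#'   standard performance tables).
#' @export
build_model_suite <- function(feature_table, labels,
                              clinical_candidates = character(0),
                              models = NULL, ...) {
  df <- as_tibble(feature_table)
  radiomic <- setdiff(names(df), c("patient_id", clinical_candidates))
  scopes <- model_suite_scopes(radiomic, clinical_candidates)
  if (!is.null(models)) {
    missing <- setdiff(models, names(scopes))
    if (length(missing)) abort(sprintf("unknown model id(s): %s",
                                       paste(missing, collapse = ", ")))
    scopes <- scopes[models]
  }
  evals <- lapply(names(scopes), function(nm) {
    cols <- c(intersect("patient_id", names(df)), scopes[[nm]])
    crossvalidate(df[cols], labels,
                  clinical_cols = intersect(clinical_candidates, scopes[[nm]]),
                  ...)
  })
  names(evals) <- names(scopes)
  structure(list(models = evals, report = suite_report(evals)),
            class = "habitat_suite")
}

suite_report <- function(evals) {
  dplyr::bind_rows(lapply(names(evals), function(nm) {
    s <- evals[[nm]]$summary
    out <- tibble(model = nm)
    for (i in seq_len(nrow(s))) out[[s$metric[i]]] <- s$mean[i]
    out
  }))
}

#' @export
print.habitat_suite <- function(x, ...) {
  cat("<habitat_suite>\n")
  print(x$report)
  invisible(x)
}
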