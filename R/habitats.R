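#' Pool region voxels across a cohort into an N x 3 intensity matrix
#'
#' Collects the (T1, T2, T1C) intensity triple of every voxel of the chosen
#' region from every patient into one tall tibble — the cohort-pooled voxel
#' matrix on which a single habitat clustering model is fitted, so habitat
#' indices are comparable across patients.
#'
#' @param patients A list; each element has `volumes` (an [multiseq_volume()])
#'   and `masks` (a [region_masks()] whose `ring` is set when pooling the
#'   peritumoral region). Names are used as patient ids when present.
#' @param region `"intratumoral"` (tumor mask) or `"peritumoral"` (ring mask).
#' @return A tibble with columns `patient_id`, `voxel` (linear index into the
#'   patient's grid), `t1`, `t2`, `t1c`; one row per region voxel per patient.
#' @export
pool_voxels <- function(patients, region = c("intratumoral", "peritumoral")) {
  region <- match.arg(region)
  ids <- names(patients) %||% sprintf("P%03d", seq_along(patients))
  rows <- lapply(seq_along(patients), function(i) {
    p <- patients[[i]]
    mask <- if (region == "intratumoral") p$masks$tumor else p$masks$ring
    if (is.null(mask)) {
      abort(sprintf("patient %s has no %s mask.", ids[i], region))
    }
    check_same_grid(mask, p$volumes$t1, c("mask", "volume"))
    idx <- which(mask > 0)
    if (length(idx) == 0) {
      abort(sprintf("patient %s has an empty %s region.", ids[i], region))
    }
    tibble(
      patient_id = ids[i], voxel = idx,
      t1 = p$volumes$t1[idx], t2 = p$volumes$t2[idx], t1c = p$volumes$t1c[idx]
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "region") <- region
  out
}

# k-means++ seeding: spread initial centres with probability proportional to
# squared distance from the nearest centre already chosen.
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centres <- matrix(NA_real_, k, ncol(x))
  centres[1, ] <- x[sample.int(n, 1), ]
  if (k == 1) return(centres)
  d2 <- rowSums((x - matrix(centres[1, ], n, ncol(x), byrow = TRUE))^2)
  for (j in 2:k) {
    tot <- sum(d2)
    pick <- if (tot <= 0) sample.int(n, 1) else sample.int(n, 1, prob = d2 / tot)
    centres[j, ] <- x[pick, ]
    d2j <- rowSums((x - matrix(centres[j, ], n, ncol(x), byrow = TRUE))^2)
    d2 <- pmin(d2, d2j)
  }
  centres
}

#' Fit K-means with k-means++ restarts
#'
#' Best-of-restarts Lloyd-style K-means on an already-standardized voxel
#' matrix. SSE is the total within-cluster sum of squared Euclidean
#' distances.
#'
#' @param x Numeric matrix (rows = voxels, columns = channels).
#' @param k Number of clusters (1 <= k <= nrow(x)).
#' @param seed RNG seed (restart initializations are drawn from it).
#' @param nstart Number of k-means++ restarts; the lowest-SSE solution wins.
#' @param iter_max Iteration cap per restart.
#' @return A list: `centroids` (k x ncol), `cluster` (integer assignment per
#'   row), `sse` (total within-cluster sum of squares), `k`, `seed`.
#' @export
fit_kmeans <- function(x, k, seed = 1, nstart = 10, iter_max = 300) {
  x <- as.matrix(x)
  if (k < 1) abort("`k` must be >= 1.")
  if (k > nrow(x)) abort(sprintf("k = %d exceeds the %d rows.", k, nrow(x)))
  if (k == 1) {
    ctr <- matrix(colMeans(x), 1, ncol(x), dimnames = list(NULL, colnames(x)))
    return(list(centroids = ctr, cluster = rep(1L, nrow(x)),
                sse = sum(sweep(x, 2, ctr[1, ])^2), k = 1L, seed = seed))
  }
  ux <- unique(x)
  if (nrow(ux) <= k) {
    # fewer distinct points than clusters: each distinct value is a cluster
    # (SSE 0); surplus centroids duplicate the first value and stay empty
    centroids <- ux[c(seq_len(nrow(ux)), rep(1L, k - nrow(ux))), , drop = FALSE]
    cl <- match(do.call(paste, as.data.frame(x)),
                do.call(paste, as.data.frame(ux)))
    return(list(centroids = unname(centroids), cluster = as.integer(cl),
                sse = 0, k = as.integer(k), seed = seed))
  }
  with_seed(seed, {
    best <- NULL
    for (r in seq_len(nstart)) {
      init <- kmeanspp_init(x, k)
      dup <- duplicated(round(init, 12))
      if (any(dup)) {
        # replace duplicate centres with unused distinct data rows
        pool <- ux[!duplicated(rbind(init[!dup, , drop = FALSE], ux))[-seq_len(sum(!dup))], , drop = FALSE]
        init[dup, ] <- pool[seq_len(sum(dup)), ]
      }
      km <- suppressWarnings(
        stats::kmeans(x, centers = init, iter.max = iter_max,
                      algorithm = "Hartigan-Wong")
      )
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
    list(centroids = unname(best$centers), cluster = as.integer(best$cluster),
         sse = best$tot.withinss, k = as.integer(k), seed = seed)
  })
}

#' Select the number of clusters by the SSE elbow rule
#'
#' The elbow is the interior candidate maximizing the discrete second
#' difference `SSE(k-1) - 2 SSE(k) + SSE(k+1)`, i.e. the point where the rate
#' of SSE decline slows most abruptly. Ties break toward the smallest k.
#'
#' @param sse Numeric vector of SSE values (length >= 3), ideally
#'   non-increasing; small Monte-Carlo violations (< 1% of the curve's range)
#'   only trigger a warning.
#' @param k Candidate cluster counts matching `sse` (default `1:length(sse)`).
#' @return The selected k (integer).
#' @export
select_k_elbow <- function(sse, k = seq_along(sse)) {
  if (length(sse) < 3) abort("SSE curve needs at least 3 candidate k values.")
  if (length(k) != length(sse)) abort("`k` and `sse` lengths differ.")
  incr <- diff(sse)
  rng <- max(sse) - min(sse)
  if (any(incr > 0)) {
    if (max(incr) > 0.01 * max(rng, .Machine$double.eps)) {
      warn("SSE curve is not non-increasing beyond Monte-Carlo tolerance.")
    }
  }
  interior <- 2:(length(sse) - 1)
  d2 <- sse[interior - 1] - 2 * sse[interior] + sse[interior + 1]
  as.integer(k[interior[which.max(d2)]])
}

#' Fit a cohort habitat model for one region
#'
#' Z-scores each channel over the pooled voxel matrix, fits K-means for every
#' candidate k (k-means++ restarts), selects k by the SSE elbow, and fixes the
#' habitat identity convention: clusters are relabelled h1..hk by ascending
#' centroid T1C value, so habitat indices are stable across runs and
#' comparable across patients.
#'
#' @param pooled Output of [pool_voxels()] (or any tibble/matrix with columns
#'   t1, t2, t1c).
#' @param region Region tag stored in the model.
#' @param k_range Candidate cluster counts (default 1:10).
#' @param seed RNG seed recorded in the model.
#' @param nstart Restarts per k.
#' @param subsample_above If the pooled matrix has more rows than this, the
#'   SSE/elbow search runs on a uniform random subsample (recorded seed) and
#'   the final model is refitted on all voxels at the selected k.
#' @return An object of class `habitat_model`.
#' @export
fit_habitat_model <- function(pooled, region = attr(pooled, "region") %||% "intratumoral",
                              k_range = 1:10, seed = 1, nstart = 10,
                              subsample_above = 2e6) {
  x <- as.matrix(as.data.frame(pooled)[, c("t1", "t2", "t1c")])
  mu <- colMeans(x)
  sdev <- apply(x, 2, sd)
  sdev[sdev <= 0] <- 1
  xs <- sweep(sweep(x, 2, mu), 2, sdev, "/")

  xfit <- xs
  sub_seed <- NULL
  if (nrow(xs) > subsample_above) {
    sub_seed <- derive_seed(seed, "elbow-subsample")
    keep <- with_seed(sub_seed, sample.int(nrow(xs), subsample_above))
    xfit <- xs[keep, , drop = FALSE]
  }

  fits <- lapply(k_range, function(k) {
    fit_kmeans(xfit, k, seed = derive_seed(seed, paste0("k", k)),
               nstart = nstart)
  })
  sse <- vapply(fits, `[[`, numeric(1), "sse")
  k_sel <- select_k_elbow(sse, k = k_range)

  final <- fits[[match(k_sel, k_range)]]
  if (!is.null(sub_seed)) {
    final <- fit_kmeans(xs, k_sel, seed = derive_seed(seed, "final"),
                        nstart = nstart)
  }
  centroids <- final$centroids
  colnames(centroids) <- c("t1", "t2", "t1c")
  ord <- order(centroids[, "t1c"])           # raw id -> position
  h_of_raw <- match(seq_len(k_sel), ord)     # raw id -> habitat index

  structure(
    list(
      region = region,
      channel_means = mu, channel_sds = sdev,
      centroids = centroids[ord, , drop = FALSE],  # row h = habitat h
      sse_curve = tibble(k = as.integer(k_range), sse = sse),
      k_selected = k_sel,
      label_order = h_of_raw,
      seed = seed,
      n_voxels = nrow(xs)
    ),
    class = "habitat_model"
  )
}

#' @export
print.habitat_model <- function(x, ...) {
  cat(sprintf("<habitat_model> region=%s, k=%d (elbow over k=%d..%d), %d pooled voxels\n",
              x$region, x$k_selected, min(x$sse_curve$k), max(x$sse_curve$k),
              x$n_voxels))
  invisible(x)
}

#' Assign habitat labels to one patient's region voxels
#'
#' Standardizes the patient's (T1, T2, T1C) triples with the model's cohort
#' parameters and labels every region voxel with the habitat index of its
#' nearest centroid. Voxels outside the region get label 0.
#'
#' @param volumes An [multiseq_volume()].
#' @param mask Logical 3D array: the region (tumor or ring) to label.
#' @param model A fitted [fit_habitat_model()] model.
#' @return Integer 3D array of habitat labels (0 outside the region), with
#'   attribute `"region"`.
#' @export
assign_habitats <- function(volumes, mask, model) {
  if (!inherits(model, "habitat_model")) abort("`model` is not a fitted habitat model.")
  stopifnot(inherits(volumes, "msvol"))
  check_same_grid(volumes$t1, mask, c("volume", "mask"))
  out <- array(0L, dim = dim(mask))
  idx <- which(mask > 0)
  if (length(idx) == 0) {
    warn("region mask is empty; returning an all-zero label map.")
    attr(out, "region") <- model$region
    return(out)
  }
  x <- cbind(volumes$t1[idx], volumes$t2[idx], volumes$t1c[idx])
  xs <- sweep(sweep(x, 2, model$channel_means), 2, model$channel_sds, "/")
  cen <- model$centroids  # row h = habitat h, already ordered
  d <- matrix(0, nrow(xs), nrow(cen))
  for (h in seq_len(nrow(cen))) {
    d[, h] <- (xs[, 1] - cen[h, 1])^2 + (xs[, 2] - cen[h, 2])^2 +
      (xs[, 3] - cen[h, 3])^2
  }
  out[idx] <- max.col(-d, ties.method = "first")
  attr(out, "region") <- model$region
  out
}

#' Serialize / restore a habitat model as JSON
#'
#' @param model A `habitat_model`.
#' @param path JSON file path.
#' @return `read_habitat_model` returns the restored model.
#' @export
write_habitat_model <- function(model, path) {
  stopifnot(inherits(model, "habitat_model"))
  obj <- model
  obj$centroids <- as.data.frame(obj$centroids)
  obj$sse_curve <- as.data.frame(obj$sse_curve)
  jsonlite::write_json(unclass(obj), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_habitat_model
#' @export
read_habitat_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$centroids <- as.matrix(obj$centroids)
  obj$channel_means <- unlist(obj$channel_means)
  obj$channel_sds <- unlist(obj$channel_sds)
  obj$sse_curve <- as_tibble(obj$sse_curve)
  structure(obj, class = "habitat_model")
}
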