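#' Names of the 107-feature radiomic panel
#'
#' The standard low-dimensional panel: shape (14), first order (18), GLCM
#' (24), GLRLM (16), GLSZM (16), NGTDM (5) and GLDM (14) features, named
#' `<Class>_<FeatureName>`.
#'
#' @return Named list of character vectors, one per feature class.
#' @export
feature_names <- function() {
  list(
    Shape = c("MeshVolume", "VoxelVolume", "SurfaceArea", "SurfaceVolumeRatio",
              "Sphericity", "Maximum3DDiameter", "Maximum2DDiameterSlice",
              "Maximum2DDiameterColumn", "Maximum2DDiameterRow",
              "MajorAxisLength", "MinorAxisLength", "LeastAxisLength",
              "Elongation", "Flatness"),
    Firstorder = c("Energy", "TotalEnergy", "Entropy", "Minimum",
                   "10Percentile", "90Percentile", "Maximum", "Mean",
                   "Median", "InterquartileRange", "Range",
                   "MeanAbsoluteDeviation", "RobustMeanAbsoluteDeviation",
                   "RootMeanSquared", "Skewness", "Kurtosis", "Variance",
                   "Uniformity"),
    GLCM = c("Autocorrelation", "JointAverage", "ClusterProminence",
             "ClusterShade", "ClusterTendency", "Contrast", "Correlation",
             "DifferenceAverage", "DifferenceEntropy", "DifferenceVariance",
             "Id", "Idm", "Idmn", "Idn", "Imc1", "Imc2", "InverseVariance",
             "JointEnergy", "JointEntropy", "MCC", "MaximumProbability",
             "SumAverage", "SumEntropy", "SumSquares"),
    GLRLM = c("ShortRunEmphasis", "LongRunEmphasis",
              "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
              "RunLengthNonUniformity", "RunLengthNonUniformityNormalized",
              "RunPercentage", "GrayLevelVariance", "RunVariance",
              "RunEntropy", "LowGrayLevelRunEmphasis",
              "HighGrayLevelRunEmphasis", "ShortRunLowGrayLevelEmphasis",
              "ShortRunHighGrayLevelEmphasis", "LongRunLowGrayLevelEmphasis",
              "LongRunHighGrayLevelEmphasis"),
    GLSZM = c("SmallAreaEmphasis", "LargeAreaEmphasis",
              "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
              "SizeZoneNonUniformity", "SizeZoneNonUniformityNormalized",
              "ZonePercentage", "GrayLevelVariance", "ZoneVariance",
              "ZoneEntropy", "LowGrayLevelZoneEmphasis",
              "HighGrayLevelZoneEmphasis", "SmallAreaLowGrayLevelEmphasis",
              "SmallAreaHighGrayLevelEmphasis", "LargeAreaLowGrayLevelEmphasis",
              "LargeAreaHighGrayLevelEmphasis"),
    NGTDM = c("Coarseness", "Contrast", "Busyness", "Complexity", "Strength"),
    GLDM = c("SmallDependenceEmphasis", "LargeDependenceEmphasis",
             "GrayLevelNonUniformity", "DependenceNonUniformity",
             "DependenceNonUniformityNormalized", "GrayLevelVariance",
             "DependenceVariance", "DependenceEntropy",
             "LowGrayLevelEmphasis", "HighGrayLevelEmphasis",
             "SmallDependenceLowGrayLevelEmphasis",
             "SmallDependenceHighGrayLevelEmphasis",
             "LargeDependenceLowGrayLevelEmphasis",
             "LargeDependenceHighGrayLevelEmphasis")
  )
}

#' @rdname feature_names
#' @export
all_feature_names <- function() {
  fn <- feature_names()
  unlist(lapply(names(fn), function(cl) paste0(cl, "_", fn[[cl]])),
         use.names = FALSE)
}

# Fixed-bin-count discretization: 32 bins spanning [min, max] of the ROI;
# the maximum maps into the top bin. A constant ROI maps entirely to bin 1.
discretize_intensities <- function(vals, n_bins = 32) {
  rng <- range(vals)
  if (rng[2] <= rng[1]) return(rep(1L, length(vals)))
  width <- (rng[2] - rng[1]) / n_bins
  pmin.int(as.integer(floor((vals - rng[1]) / width)) + 1L, n_bins)
}

#' Extract the 107-feature radiomic panel for one subregion
#'
#' Computes shape features from the mask geometry, first-order features from
#' the raw intensity histogram, and the five texture-matrix classes (GLCM,
#' GLRLM, GLSZM, NGTDM, GLDM) from intensities discretized to a fixed bin
#' count. Texture matrices use the 13 unique 3D directions at Chebyshev
#' distance 1; direction-dependent classes average the feature value over
#' directions.
#'
#' Subregions smaller than `min_voxels` return an all-missing vector (texture
#' matrices degenerate on tiny regions); the reason is attached as attribute
#' `"missing_reason"`.
#'
#' @param image 3D numeric array of intensities.
#' @param mask Logical/binary 3D array on the same grid: the subregion.
#' @param spacing_mm Voxel spacing in mm.
#' @param n_bins Fixed bin count for discretization (default 32).
#' @param min_voxels Minimum subregion size (default 10).
#' @return Named numeric vector of 107 features (`<Class>_<Name>`).
#' @export
extract_features <- function(image, mask, spacing_mm = c(1, 1, 1),
                             n_bins = 32, min_voxels = 10) {
  stop_if_not_grid3d(image, "image")
  check_same_grid(image, mask, c("image", "mask"))
  mask <- mask > 0
  nm <- all_feature_names()
  n <- sum(mask)
  if (n == 0) {
    out <- stats::setNames(rep(NA_real_, length(nm)), nm)
    attr(out, "missing_reason") <- "empty subregion"
    return(out)
  }
  if (n < min_voxels) {
    out <- stats::setNames(rep(NA_real_, length(nm)), nm)
    attr(out, "missing_reason") <- sprintf("subregion has %d < %d voxels", n, min_voxels)
    return(out)
  }
  vals <- image[mask]
  if (any(!is.finite(vals))) abort("image is not finite on the subregion.")

  # crop to the mask bounding box: all texture work happens on the crop
  ind <- which(mask, arr.ind = TRUE)
  lo <- apply(ind, 2, min); hi <- apply(ind, 2, max)
  mcrop <- mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  icrop <- image[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  dim(mcrop) <- c(hi - lo + 1L)
  dim(icrop) <- c(hi - lo + 1L)
  gl <- array(NA_integer_, dim = dim(mcrop))
  gl[mcrop] <- discretize_intensities(icrop[mcrop], n_bins)

  out <- c(
    shape_features(mcrop, spacing_mm),
    firstorder_features(vals, gl[mcrop], spacing_mm),
    glcm_features(gl),
    glrlm_features(gl),
    glszm_features(gl),
    ngtdm_features(gl),
    gldm_features(gl)
  )
  stats::setNames(out, nm)
}

# ---- shape (mask geometry only) --------------------------------------------

# Voxel-based shape descriptors: volume by voxel count, surface area by
# exposed-face count, diameters over boundary-voxel centres, axis lengths
# from the eigenvalues of the physical-coordinate covariance (scaled by 4).
shape_features <- function(mask, spacing) {
  n <- sum(mask)
  vol <- n * prod(spacing)
  dims <- dim(mask)

  pad <- array(FALSE, dims + 2L)
  pad[2:(dims[1] + 1), 2:(dims[2] + 1), 2:(dims[3] + 1)] <- mask
  face_area <- c(spacing[2] * spacing[3], spacing[1] * spacing[3],
                 spacing[1] * spacing[2])
  area <- 0
  exposed_any <- array(FALSE, dims)
  for (a in 1:3) {
    for (s in c(-1L, 1L)) {
      d <- c(0L, 0L, 0L); d[a] <- s
      b <- block_ranges(dim(pad), d)
      sh <- shifted_blocks(pad, d)
      exp_faces <- array(FALSE, dim(pad))
      exp_faces[b$centre[[1]], b$centre[[2]], b$centre[[3]]] <-
        sh$centre & !sh$neighbour
      exp_faces <- exp_faces[2:(dims[1] + 1), 2:(dims[2] + 1),
                             2:(dims[3] + 1), drop = FALSE]
      area <- area + sum(exp_faces) * face_area[a]
      exposed_any <- exposed_any | exp_faces
    }
  }

  sphericity <- (36 * pi * vol^2)^(1 / 3) / area
  sv_ratio <- area / vol

  idx <- which(mask, arr.ind = TRUE)
  coords <- sweep(idx - 1, 2, spacing, "*")
  bcoords <- coords[exposed_any[mask], , drop = FALSE]
  if (nrow(bcoords) == 0) bcoords <- coords

  d3 <- max_pairwise_distance(bcoords)
  d_slice <- max_pairwise_distance_2d(bcoords[, c(1, 2), drop = FALSE])
  d_row <- max_pairwise_distance_2d(bcoords[, c(1, 3), drop = FALSE])
  d_col <- max_pairwise_distance_2d(bcoords[, c(2, 3), drop = FALSE])

  if (nrow(coords) > 1) {
    ev <- sort(eigen(stats::cov(coords), symmetric = TRUE,
                     only.values = TRUE)$values, decreasing = TRUE)
    ev <- pmax(ev, 0)
  } else {
    ev <- c(0, 0, 0)
  }
  major <- 4 * sqrt(ev[1]); minor <- 4 * sqrt(ev[2]); least <- 4 * sqrt(ev[3])
  elong <- if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 0
  flat <- if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 0

  c(vol, vol, area, sv_ratio, sphericity, d3, d_slice, d_col, d_row,
    major, minor, least, elong, flat)
}

# Chunked exact maximum pairwise Euclidean distance (memory-bounded). The
# diameter is attained on the convex hull, so prune first to points that are
# extreme along a fixed fan of directions plus the coordinate axes; the exact
# pairwise maximum is then computed over the pruned set.
max_pairwise_distance <- function(p) {
  n <- nrow(p)
  if (n < 2) return(0)
  if (n > 400) {
    u <- fibonacci_directions(120)
    proj <- p %*% t(u)
    keep <- unique(c(apply(proj, 2, which.max), apply(proj, 2, which.min)))
    # pruning by direction extremes can miss hull vertices on near-flat
    # facets; augment with the per-axis extremes to stay safe on boxes
    for (a in seq_len(ncol(p))) {
      keep <- c(keep, which(p[, a] == max(p[, a])), which(p[, a] == min(p[, a])))
    }
    p <- p[unique(keep), , drop = FALSE]
    n <- nrow(p)
  }
  sq <- rowSums(p^2)
  best <- 0
  chunk <- max(1L, floor(5e6 / n))
  for (s in seq(1, n, by = chunk)) {
    cs <- s:min(s + chunk - 1, n)
    d2 <- -2 * tcrossprod(p[cs, , drop = FALSE], p)
    d2 <- sweep(d2, 2, sq, "+") + sq[cs]
    best <- max(best, max(d2))
  }
  sqrt(max(best, 0))
}

# 2D diameter via the exact convex hull.
max_pairwise_distance_2d <- function(p) {
  if (nrow(p) < 2) return(0)
  hull <- grDevices::chull(p[, 1], p[, 2])
  max_pairwise_exact(p[hull, , drop = FALSE])
}

max_pairwise_exact <- function(p) {
  n <- nrow(p)
  if (n < 2) return(0)
  sq <- rowSums(p^2)
  d2 <- -2 * tcrossprod(p) + outer(sq, sq, "+")
  sqrt(max(max(d2), 0))
}

# Deterministic quasi-uniform directions on the sphere (Fibonacci lattice).
fibonacci_directions <- function(k) {
  i <- seq_len(k) - 0.5
  phi <- acos(1 - 2 * i / k)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# ---- first order ------------------------------------------------------------

firstorder_features <- function(vals, gl, spacing) {
  n <- length(vals)
  mu <- mean(vals)
  m2 <- mean((vals - mu)^2)             # population variance
  m3 <- mean((vals - mu)^3)
  m4 <- mean((vals - mu)^4)
  p <- tabulate(gl) / n
  p <- p[p > 0]
  q <- quantile(vals, c(0.10, 0.25, 0.75, 0.90), names = FALSE)
  robust <- vals[vals >= q[1] & vals <= q[4]]
  energy <- sum(vals^2)
  c(
    Energy = energy,
    TotalEnergy = prod(spacing) * energy,
    Entropy = -sum(p * log2(p)),
    Minimum = min(vals),
    P10 = q[1],
    P90 = q[4],
    Maximum = max(vals),
    Mean = mu,
    Median = median(vals),
    IQR = q[3] - q[2],
    Range = max(vals) - min(vals),
    MAD = mean(abs(vals - mu)),
    rMAD = if (length(robust)) mean(abs(robust - mean(robust))) else 0,
    RMS = sqrt(mean(vals^2)),
    Skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    Kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    Variance = m2,
    Uniformity = sum(p^2)
  )
}
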