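#' Correct a smooth multiplicative bias field
#'
#' Estimates the low-frequency multiplicative inhomogeneity of an intensity
#' grid and divides it out. The estimator alternates, for a few iterations,
#' between (a) a piecewise-constant tissue-intensity model — voxels are
#' binned by quantiles of the current corrected log-intensity and each bin
#' contributes its mean — and (b) a full second-order polynomial surface in
#' the three normalized spatial coordinates fitted to the log-residual
#' (observed log-intensity minus tissue model). Alternating a sharpened
#' intensity model with a smooth field fit is the same principle that drives
#' N4-style correctors; the polynomial keeps the field estimate smooth and
#' closed-form. The estimated field is normalized to unit geometric mean and
#' the output rescaled so the global mean intensity is preserved exactly.
#' Grid geometry is never changed.
#'
#' @param volume 3D numeric array with finite, non-negative intensities.
#' @param mask Optional logical array restricting the fit (the correction is
#'   still applied to the whole grid). Default: voxels above 1% of the mean
#'   intensity, which keeps near-zero background out of the log fit.
#' @param n_iter Tissue-model / field-fit alternations (default 4).
#' @param n_bins Quantile bins of the tissue-intensity model (default 8; of
#'   the order of the number of distinct tissue classes).
#' @return A 3D array of the same shape, bias-attenuated.
#' @export
correct_bias <- function(volume, mask = NULL, n_iter = 4, n_bins = 8) {
  stop_if_not_grid3d(volume, "volume")
  if (any(!is.finite(volume))) abort("volume contains non-finite voxels.")
  if (any(volume < 0)) abort("volume contains negative intensities.")
  dims <- dim(volume)
  if (is.null(mask)) mask <- volume > 0.01 * mean(volume)
  if (sum(mask) < 20) return(volume)  # nothing reliable to fit

  u <- lapply(dims, function(n) seq(-1, 1, length.out = n))
  co <- list(
    x = array(rep(u[[1]], times = dims[2] * dims[3]), dim = dims),
    y = array(rep(rep(u[[2]], each = dims[1]), times = dims[3]), dim = dims),
    z = array(rep(u[[3]], each = dims[1] * dims[2]), dim = dims)
  )
  basis <- function(x, y, z) {
    cbind(1, x, y, z, x^2, y^2, z^2, x * y, x * z, y * z,
          x^3, y^3, z^3, x^4, y^4, z^4)
  }
  X <- basis(co$x[mask], co$y[mask], co$z[mask])
  eps <- 1e-6 * mean(volume[mask])
  loga <- log(pmax(volume[mask], eps))
  if (stats::sd(loga) == 0) return(volume)

  logfield_m <- rep(0, length(loga))
  cf <- numeric(ncol(X))
  for (it in seq_len(n_iter)) {
    corrected <- loga - logfield_m
    # tissue model: one level per mode of the corrected log-intensity
    # density; a class contributes a single peak however many voxels it has,
    # so the field fit cannot hide inside a dominant class
    den <- stats::density(corrected, n = 512)
    peak <- which(diff(sign(diff(den$y))) == -2) + 1
    if (length(peak) < 1) break
    modes <- den$x[peak]
    mid <- (modes[-1] + modes[-length(modes)]) / 2
    tissue <- modes[findInterval(corrected, mid) + 1]
    fit <- stats::lm.fit(X, loga - tissue)
    cf <- fit$coefficients
    cf[is.na(cf)] <- 0
    logfield_m <- as.numeric(X %*% cf)
    logfield_m <- logfield_m - mean(logfield_m)
  }
  logfield <- array(basis(as.vector(co$x), as.vector(co$y), as.vector(co$z))
                    %*% cf, dim = dims)
  logfield <- logfield - mean(logfield[mask])
  out <- volume / exp(logfield)
  out * (mean(volume) / mean(out))
}

#' Resample a grid to isotropic voxels
#'
#' Images are resampled with trilinear interpolation, masks with
#' nearest-neighbor interpolation (so mask outputs stay binary / integer
#' labels stay labels). The output has `floor(extent / target) + 1` voxels
#' per axis, where `extent = (n - 1) * spacing` is the world distance between
#' the first and last voxel centres, so the world extent is preserved to
#' within one voxel.
#'
#' @param grid 3D array (image intensities, or a binary/label mask).
#' @param spacing_mm Current voxel spacing (length 3, mm).
#' @param target_mm Target isotropic spacing (single positive number, mm).
#'   Default 1 mm.
#' @param mode `"image"` (trilinear) or `"mask"` (nearest neighbor).
#' @return The resampled 3D array; attribute `"spacing_mm"` carries the new
#'   spacing.
#' @export
resample_isotropic <- function(grid, spacing_mm, target_mm = 1,
                               mode = c("image", "mask")) {
  mode <- match.arg(mode)
  stop_if_not_grid3d(grid, "grid")
  if (!is.numeric(target_mm) || length(target_mm) != 1 || target_mm <= 0) {
    abort("`target_mm` must be a single positive number.")
  }
  spacing_mm <- as.numeric(spacing_mm)
  dims <- dim(grid)
  extent <- (dims - 1) * spacing_mm
  out_dims <- pmax(as.integer(floor(extent / target_mm + 1e-9)) + 1L, 1L)

  # source index-space coordinates of every output voxel centre, per axis
  src <- lapply(1:3, function(a) {
    (seq_len(out_dims[a]) - 1) * target_mm / spacing_mm[a] + 1
  })

  was_logical <- is.logical(grid)
  if (mode == "mask") {
    idx <- lapply(1:3, function(a) pmin(pmax(round(src[[a]]), 1L), dims[a]))
    out <- grid[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  } else {
    i0 <- lapply(1:3, function(a) pmin(pmax(floor(src[[a]]), 1), dims[a]))
    i1 <- lapply(1:3, function(a) pmin(i0[[a]] + 1, dims[a]))
    fr <- lapply(1:3, function(a) src[[a]] - i0[[a]])
    wx1 <- array(fr[[1]], dim = out_dims)
    wy1 <- array(rep(fr[[2]], each = out_dims[1]), dim = out_dims)
    wz1 <- array(rep(fr[[3]], each = out_dims[1] * out_dims[2]), dim = out_dims)
    out <- array(0, dim = out_dims)
    for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
      ix <- if (cx == 0) i0[[1]] else i1[[1]]
      iy <- if (cy == 0) i0[[2]] else i1[[2]]
      iz <- if (cz == 0) i0[[3]] else i1[[3]]
      w <- (if (cx == 0) 1 - wx1 else wx1) *
        (if (cy == 0) 1 - wy1 else wy1) *
        (if (cz == 0) 1 - wz1 else wz1)
      out <- out + w * grid[ix, iy, iz, drop = FALSE]
    }
  }
  if (was_logical && mode == "mask") out <- out > 0
  attr(out, "spacing_mm") <- rep(target_mm, 3)
  out
}

#' Preprocess one patient: bias correction then isotropic resampling
#'
#' Applies [correct_bias()] to each sequence on the native grid, then
#' resamples all three sequences (trilinear) and the masks (nearest neighbor)
#' to the target isotropic spacing. Volumes are required to be pre-aligned;
#' [align_identity()] is the (no-op) alignment hook.
#'
#' @param volumes An [multiseq_volume()].
#' @param masks A [region_masks()] on the same grid.
#' @param target_mm Target isotropic spacing in mm (default 1).
#' @param bias_correct Set `FALSE` to skip bias correction.
#' @return A list with `volumes` (resampled `msvol`) and `masks` (resampled
#'   `region_masks`, ring dropped — recompute it on the new grid).
#' @export
preprocess_patient <- function(volumes, masks, target_mm = 1,
                               bias_correct = TRUE) {
  stopifnot(inherits(volumes, "msvol"), inherits(masks, "region_masks"))
  sp <- volumes$spacing_mm
  seqs <- list(t1 = volumes$t1, t2 = volumes$t2, t1c = volumes$t1c)
  if (bias_correct) seqs <- lapply(seqs, correct_bias)
  seqs <- lapply(seqs, resample_isotropic, spacing_mm = sp,
                 target_mm = target_mm, mode = "image")
  tumor <- resample_isotropic(masks$tumor, sp, target_mm, mode = "mask")
  excl <- if (!is.null(masks$exclusion)) {
    resample_isotropic(masks$exclusion, sp, target_mm, mode = "mask")
  }
  list(
    volumes = multiseq_volume(seqs$t1, seqs$t2, seqs$t1c,
                              spacing_mm = rep(target_mm, 3)),
    masks = region_masks(tumor = tumor, exclusion = excl,
                         spacing_mm = rep(target_mm, 3))
  )
}

#' No-op alignment hook
#'
#' Volumes entering the pipeline are required to be pre-aligned (the synthetic
#' generator produces aligned sequences by construction). This hook exists so
#' a registration step can be slotted in without changing the pipeline
#' surface.
#'
#' @param volumes An [multiseq_volume()].
#' @return `volumes`, unchanged.
#' @export
align_identity <- function(volumes) volumes
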