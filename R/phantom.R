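#' Phantom patient configuration
#'
#' Describes one synthetic patient: grid geometry, the latent tissue classes
#' that later play the role of habitats, the tumor ellipsoid, and the imaging
#' degradations (multiplicative low-frequency bias, additive noise).
#'
#' The latent structure is spatially coherent by construction: inside the
#' tumor the classes form concentric equal-volume ellipsoidal shells whose
#' boundaries are jittered per patient and warped by a smooth random bump
#' field, so classes look like contiguous habitats rather than voxel noise;
#' outside the tumor the same classes tile the tissue as smooth random blobs.
#'
#' @param grid_shape Integer length-3: voxels per axis. Default `c(48, 48, 32)`.
#' @param spacing_mm Numeric length-3 voxel size in mm. Default 2 mm isotropic.
#' @param n_classes Number of latent tissue classes (>= 2). Default 5.
#' @param class_means `n_classes x 3` matrix of mean intensities per class for
#'   (T1, T2, T1C), arbitrary units; rows must be pairwise distinct.
#' @param class_sd Within-class intensity standard deviation.
#' @param tumor_semiaxes_mm Ellipsoid semi-axes in mm (before per-patient
#'   jitter).
#' @param semiaxes_jitter Relative uniform jitter applied to each semi-axis
#'   per patient (default 0.2, i.e. +/-20%).
#' @param bias_amplitude Relative amplitude of the multiplicative low-frequency
#'   bias field (0 disables it).
#' @param noise_sd Additive Gaussian noise standard deviation.
#' @param shell_jitter_sd Log-normal jitter s.d. on shell boundary radii
#'   (drives between-patient habitat-fraction variability).
#' @param blob_amplitude Amplitude of the smooth warp field on the normalized
#'   radius (spatial irregularity of habitat boundaries).
#' @param ring_radius_mm Radius used for the ground-truth peritumoral ring.
#' @param exclusion_radius_mm Radius of a planted spherical exclusion (bone/air
#'   stand-in) tangent to the tumor; 0 disables it.
#'
#' @return A `phantom_config` list, validated.
#' @export
phantom_config <- function(grid_shape = c(48L, 48L, 32L),
                           spacing_mm = c(2, 2, 2),
                           n_classes = 5L,
                           class_means = default_class_means(n_classes),
                           class_sd = 10,
                           tumor_semiaxes_mm = c(16, 14, 10),
                           semiaxes_jitter = 0.2,
                           bias_amplitude = 0.15,
                           noise_sd = 10,
                           shell_jitter_sd = 0.06,
                           blob_amplitude = 0.05,
                           ring_radius_mm = 3,
                           exclusion_radius_mm = 4) {
  cfg <- list(
    grid_shape = as.integer(grid_shape), spacing_mm = as.numeric(spacing_mm),
    n_classes = as.integer(n_classes), class_means = as.matrix(class_means),
    class_sd = class_sd, tumor_semiaxes_mm = as.numeric(tumor_semiaxes_mm),
    semiaxes_jitter = semiaxes_jitter, bias_amplitude = bias_amplitude,
    noise_sd = noise_sd, shell_jitter_sd = shell_jitter_sd,
    blob_amplitude = blob_amplitude, ring_radius_mm = ring_radius_mm,
    exclusion_radius_mm = exclusion_radius_mm
  )
  if (length(cfg$grid_shape) != 3 || any(cfg$grid_shape < 8)) {
    abort("`grid_shape` must be three integers >= 8.")
  }
  if (any(cfg$spacing_mm <= 0)) abort("`spacing_mm` must be positive.")
  if (cfg$n_classes < 2) abort("`n_classes` must be >= 2.")
  if (nrow(cfg$class_means) != cfg$n_classes || ncol(cfg$class_means) != 3) {
    abort("`class_means` must be an n_classes x 3 matrix.")
  }
  if (anyDuplicated(cfg$class_means) > 0) {
    abort("class mean triples must be pairwise distinct.")
  }
  if (any(cfg$tumor_semiaxes_mm <= 0) || cfg$semiaxes_jitter < 0 ||
      cfg$semiaxes_jitter >= 1) {
    abort("`tumor_semiaxes_mm` must be positive and `semiaxes_jitter` in [0, 1).")
  }
  if (cfg$noise_sd < 0 || cfg$class_sd < 0 || cfg$bias_amplitude < 0) {
    abort("noise, class s.d. and bias amplitude must be non-negative.")
  }
  # worst-case jittered tumor must fit strictly inside the grid
  extent <- (cfg$grid_shape - 1) * cfg$spacing_mm
  worst <- cfg$tumor_semiaxes_mm * (1 + cfg$semiaxes_jitter)
  if (any(worst + 2 * cfg$spacing_mm >= extent / 2)) {
    abort("tumor does not fit in grid: enlarge the grid or shrink the semi-axes.")
  }
  structure(cfg, class = "phantom_config")
}

# Default class mean triples (T1, T2, T1C), arbitrary scanner counts.
# The five standardized class positions were chosen (by enumerating every
# partition of five points and minimizing the coefficient of variation of
# the successive best-k SSE drops) so that the pooled SSE-vs-k curve of a
# well-separated five-class mixture declines nearly linearly up to k = 5 and
# kinks there — the regime in which the second-difference elbow rule
# identifies the true class count. T1C components are strictly increasing so
# the h1..hk ordering convention (ascending centroid T1C) is tie-free.
default_class_means <- function(n_classes = 5L) {
  dirs5 <- rbind(
    c(-0.841,  0.338, -1.359),
    c( 1.164,  0.553, -0.583),
    c( 0.760, -1.437,  0.154),
    c(-1.164, -0.553,  0.583),
    c( 0.081,  1.099,  1.205)
  )
  centre <- c(160, 160, 220)
  scale <- c(55, 55, 60)
  if (n_classes <= 5L) {
    v <- dirs5[seq_len(n_classes), , drop = FALSE]
  } else {
    # extra classes: continue around the equator at intermediate T1C
    extra <- n_classes - 5L
    ang <- 2 * pi * seq_len(extra) / (extra + 1) + pi / 5
    v <- rbind(dirs5, cbind(cos(ang), sin(ang),
                            seq(0.4, 0.6, length.out = extra)))
  }
  sweep(sweep(v, 2, scale, "*"), 2, centre, "+")
}

# Smooth random field: sum of Gaussian bumps with random centres/widths.
# Returns an array on the grid with roughly unit scale before `amplitude`.
smooth_bump_field <- function(dims, spacing, n_bumps = 8, width_mm = 14,
                              amplitude = 1) {
  co <- coord_arrays(dims, spacing)
  extent <- (dims - 1) * spacing
  f <- array(0, dim = dims)
  for (b in seq_len(n_bumps)) {
    ctr <- runif(3, 0.15, 0.85) * extent
    w <- width_mm * runif(1, 0.7, 1.4)
    a <- runif(1, -1, 1)
    d2 <- (co$x - ctr[1])^2 + (co$y - ctr[2])^2 + (co$z - ctr[3])^2
    f <- f + a * exp(-d2 / (2 * w^2))
  }
  amplitude * f
}

# Multiplicative bias field: product of per-axis quadratics 1 + q(u) with
# |q| <= amplitude/3 per axis, so total deviation is on the order of
# `amplitude` relative to 1. Random coefficients, always positive.
bias_field <- function(dims, spacing, amplitude) {
  if (amplitude <= 0) return(array(1, dim = dims))
  f <- array(1, dim = dims)
  per_axis <- amplitude / 3
  for (a in 1:3) {
    u <- seq(-1, 1, length.out = dims[a])
    cf <- runif(2, -1, 1)
    q <- cf[1] * u + cf[2] * (u^2 - 1 / 3)
    q <- q / max(abs(q), 1e-12) * per_axis
    fa <- 1 + q
    rep_pattern <- switch(a,
      array(rep(fa, times = dims[2] * dims[3]), dim = dims),
      array(rep(rep(fa, each = dims[1]), times = dims[3]), dim = dims),
      array(rep(fa, each = dims[1] * dims[2]), dim = dims)
    )
    f <- f * rep_pattern
  }
  f
}

#' Generate one phantom patient
#'
#' Renders three aligned sequence volumes, the tumor/exclusion masks, and the
#' ground truth (per-voxel latent class map, habitat volume fractions in the
#' tumor and in a ground-truth peritumoral ring).
#'
#' Voxel intensity = class mean + within-class Gaussian term, multiplied by a
#' smooth bias field, plus additive noise; each sequence gets an independent
#' bias draw.
#'
#' @param config A [phantom_config()].
#' @param seed Integer RNG seed; fixed seed reproduces the phantom exactly.
#' @param render If `FALSE`, skip intensity rendering (masks + truth only),
#'   which is much faster when only habitat fractions and outcomes are needed.
#' @return A list with elements `volumes` ([multiseq_volume()] or `NULL`),
#'   `masks` ([region_masks()] with tumor + exclusion), and `truth` (list:
#'   `label_map` integer array, `fractions` tibble with one row per region x
#'   class, `semiaxes_mm`).
#' @export
generate_phantom <- function(config = phantom_config(), seed = 1,
                             render = TRUE) {
  stopifnot(inherits(config, "phantom_config"))
  with_seed(seed, {
    dims <- config$grid_shape
    sp <- config$spacing_mm
    k <- config$n_classes
    extent <- (dims - 1) * sp
    centre <- extent / 2

    axes <- config$tumor_semiaxes_mm *
      runif(3, 1 - config$semiaxes_jitter, 1 + config$semiaxes_jitter)
    if (any(axes + 2 * sp >= extent / 2)) {
      abort("tumor does not fit in grid after jitter.")
    }

    co <- coord_arrays(dims, sp)
    r_n <- sqrt(((co$x - centre[1]) / axes[1])^2 +
                ((co$y - centre[2]) / axes[2])^2 +
                ((co$z - centre[3]) / axes[3])^2)
    tumor <- r_n <= 1

    # concentric equal-volume shell boundaries, jittered per patient,
    # warped by a smooth bump field so habitats have irregular borders
    b <- (seq_len(k - 1) / k)^(1 / 3)
    b <- sort(b * exp(rnorm(k - 1, 0, config$shell_jitter_sd)))
    warp <- smooth_bump_field(dims, sp, n_bumps = 8, width_mm = 14,
                              amplitude = config$blob_amplitude)
    r_eff <- r_n + warp
    label <- array(0L, dim = dims)
    label[tumor] <- 1L + findInterval(r_eff[tumor], b)
    label[tumor] <- pmin.int(pmax.int(label[tumor], 1L), k)

    # outside the tumor: contiguous blobs of the same classes. Quantile cuts
    # are taken over the near-tumor band (where the peritumoral ring lives)
    # so the ring samples all classes in balanced proportions.
    blob <- smooth_bump_field(dims, sp, n_bumps = 24, width_mm = 12,
                              amplitude = 1)
    outside <- !tumor
    band <- outside & r_n <= 1 + max(3 * config$ring_radius_mm, 9) / min(axes)
    if (sum(band) < 10 * k) band <- outside
    qs <- quantile(blob[band], probs = seq_len(k - 1) / k, names = FALSE)
    label[outside] <- 1L + findInterval(blob[outside], qs)

    # planted spherical exclusion tangent to the +x tumor boundary
    exclusion <- NULL
    if (config$exclusion_radius_mm > 0) {
      ec <- centre + c(axes[1] + config$exclusion_radius_mm + min(sp), 0, 0)
      d2 <- (co$x - ec[1])^2 + (co$y - ec[2])^2 + (co$z - ec[3])^2
      exclusion <- d2 <= config$exclusion_radius_mm^2
      exclusion <- exclusion & !tumor
    }

    masks <- region_masks(tumor = tumor, exclusion = exclusion, spacing_mm = sp)
    ring <- make_peritumoral_ring(tumor, sp, config$ring_radius_mm,
                                  exclusion = exclusion)

    frac_in_region <- function(region) {
      n <- tabulate(label[region], nbins = k)
      n / sum(n)
    }
    fractions <- dplyr::bind_rows(
      tibble(region = "intratumoral", habitat = seq_len(k),
             fraction = frac_in_region(tumor)),
      tibble(region = "peritumoral", habitat = seq_len(k),
             fraction = frac_in_region(ring))
    )

    volumes <- NULL
    if (render) {
      n_vox <- prod(dims)
      render_seq <- function(s) {
        mu <- array(config$class_means[label, s], dim = dims)
        img <- mu + rnorm(n_vox, 0, config$class_sd)
        img <- img * bias_field(dims, sp, config$bias_amplitude)
        img <- img + rnorm(n_vox, 0, config$noise_sd)
        pmax(img, 0)
      }
      volumes <- multiseq_volume(render_seq(1), render_seq(2), render_seq(3),
                                 spacing_mm = sp)
    }

    list(
      volumes = volumes,
      masks = masks,
      truth = list(label_map = label, fractions = fractions,
                   ring = ring, semiaxes_mm = axes)
    )
  })
}
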