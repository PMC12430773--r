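#' Construct the peritumoral ring by metric dilation of the tumor mask
#'
#' The ring is the set of voxels whose Euclidean distance to the nearest tumor
#' voxel, measured in millimetres and honoring anisotropic voxel spacing, lies
#' in `(0, radius_mm]`, minus any voxels in the exclusion mask. Equivalently it
#' is the dilation of the tumor by the lattice ball of radius `radius_mm`,
#' clipped to the grid, with the tumor itself removed: a voxel `v` is within
#' distance `r` of the tumor exactly when some tumor voxel `t` satisfies
#' `||v - t|| <= r`, so dilating by the set of integer offsets with physical
#' length `<= r` reproduces the distance-threshold definition exactly.
#'
#' @param tumor Logical/binary 3D array, non-empty.
#' @param spacing_mm Voxel spacing in mm (length 3).
#' @param radius_mm Ring radius in mm (>= 0); the boundary `d == radius_mm` is
#'   included. Default 3 mm.
#' @param exclusion Optional logical 3D array of voxels that can never belong
#'   to the ring (bone, air cavities).
#' @return Logical 3D array: the ring mask. Disjoint from both the tumor and
#'   the exclusion mask by construction.
#' @export
make_peritumoral_ring <- function(tumor, spacing_mm, radius_mm = 3,
                                  exclusion = NULL) {
  stop_if_not_grid3d(tumor, "tumor")
  tumor <- tumor > 0
  if (!any(tumor)) abort("tumor mask is empty.")
  if (!is.numeric(radius_mm) || length(radius_mm) != 1 || radius_mm < 0) {
    abort("`radius_mm` must be a single non-negative number.")
  }
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3 || any(spacing_mm <= 0)) {
    abort("`spacing_mm` must be three positive numbers.")
  }
  if (!is.null(exclusion)) {
    check_same_grid(tumor, exclusion, c("tumor", "exclusion"))
    exclusion <- exclusion > 0
  }

  offs <- ball_offsets(spacing_mm, radius_mm)
  dims <- dim(tumor)
  dilated <- array(FALSE, dim = dims)
  for (i in seq_len(nrow(offs))) {
    d <- offs[i, ]
    b <- block_ranges(dims, d)
    # voxel v = t + d is covered when t is tumor: write into the shifted block
    dilated[b$neighbour[[1]], b$neighbour[[2]], b$neighbour[[3]]] <-
      dilated[b$neighbour[[1]], b$neighbour[[2]], b$neighbour[[3]]] |
      tumor[b$centre[[1]], b$centre[[2]], b$centre[[3]]]
  }
  ring <- dilated & !tumor
  if (!is.null(exclusion)) ring <- ring & !exclusion
  ring
}

# Integer offsets whose physical length is in (0, radius] for the given
# anisotropic spacing.
ball_offsets <- function(spacing_mm, radius_mm) {
  kmax <- floor(radius_mm / spacing_mm)
  g <- as.matrix(expand.grid(
    dx = -kmax[1]:kmax[1], dy = -kmax[2]:kmax[2], dz = -kmax[3]:kmax[3]
  ))
  d2 <- (g[, 1] * spacing_mm[1])^2 + (g[, 2] * spacing_mm[2])^2 +
    (g[, 3] * spacing_mm[3])^2
  keep <- d2 > 0 & d2 <= radius_mm^2 + 1e-9
  unname(g[keep, , drop = FALSE])
}
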