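#' @importFrom rlang %||% abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom stats cor median quantile rnorm runif rlogis rpois sd var
NULL

# Run code under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Derive a deterministic child seed from a master seed and a stream label.
# Kept strictly below 2^31 so it is always a valid R integer seed.
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(as.character(stream)) * (31L^(seq_along(utf8ToInt(as.character(stream))) %% 7L)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

# 13 unique 3D lattice directions at Chebyshev distance 1 (one per +/- pair).
unique_directions_3d <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  keep <- g[, 3] > 0 | (g[, 3] == 0 & g[, 2] > 0) |
    (g[, 3] == 0 & g[, 2] == 0 & g[, 1] > 0)
  unname(g[keep, , drop = FALSE])
}

# All 26 signed neighbour offsets.
all_directions_3d <- function() {
  u <- unique_directions_3d()
  rbind(u, -u)
}

# Index ranges selecting the in-bounds centre block and its shifted
# counterpart for an integer offset d on an array of dimensions `dims`.
block_ranges <- function(dims, d) {
  ctr <- vector("list", 3)
  nbr <- vector("list", 3)
  for (a in 1:3) {
    if (dims[a] <= abs(d[a])) {
      ctr[[a]] <- integer(0)
    } else if (d[a] >= 0) {
      ctr[[a]] <- seq_len(dims[a] - d[a])
    } else {
      ctr[[a]] <- seq.int(1 - d[a], dims[a])
    }
    nbr[[a]] <- ctr[[a]] + d[a]
  }
  list(centre = ctr, neighbour = nbr)
}

# Extract the centre/neighbour sub-blocks of a 3D array for offset d.
shifted_blocks <- function(arr, d) {
  b <- block_ranges(dim(arr), d)
  list(
    centre = arr[b$centre[[1]], b$centre[[2]], b$centre[[3]], drop = FALSE],
    neighbour = arr[b$neighbour[[1]], b$neighbour[[2]], b$neighbour[[3]], drop = FALSE]
  )
}

# World coordinates (mm) of voxel centres along one axis.
axis_world <- function(n, spacing, origin = 0) origin + (seq_len(n) - 1) * spacing

# Coordinate arrays (same shape as the grid) in mm.
coord_arrays <- function(dims, spacing, origin = c(0, 0, 0)) {
  x <- axis_world(dims[1], spacing[1], origin[1])
  y <- axis_world(dims[2], spacing[2], origin[2])
  z <- axis_world(dims[3], spacing[3], origin[3])
  list(
    x = array(rep(x, times = dims[2] * dims[3]), dim = dims),
    y = array(rep(rep(y, each = dims[1]), times = dims[3]), dim = dims),
    z = array(rep(z, each = dims[1] * dims[2]), dim = dims)
  )
}

stop_if_not_grid3d <- function(x, what = "volume") {
  if (!is.array(x) || length(dim(x)) != 3) {
    abort(sprintf("`%s` must be a 3D array.", what))
  }
}

check_same_grid <- function(a, b, what = c("grid A", "grid B")) {
  if (!identical(dim(a), dim(b))) {
    abort(sprintf("%s and %s are on different grids (%s vs %s).",
                  what[1], what[2],
                  paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")))
  }
}
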