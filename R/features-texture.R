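# Texture-matrix feature classes on a cropped, discretized subregion.
# `gl` is an integer array with gray levels 1..Ng inside the subregion and
# NA outside. All matrices follow the standard IBSI-consistent definitions
# with a 26-neighbourhood (13 unique directions, distance 1); GLCM and GLRLM
# are computed per direction and the feature values averaged over directions.

eps_log <- 2.2e-16

# ---- GLCM -------------------------------------------------------------------

glcm_features <- function(gl) {
  L <- max(gl, na.rm = TRUE)
  dirs <- unique_directions_3d()
  feats <- NULL
  n_used <- 0
  acc <- numeric(24)
  for (i in seq_len(nrow(dirs))) {
    sh <- shifted_blocks(gl, dirs[i, ])
    a <- sh$centre; b <- sh$neighbour
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) next
    counts <- tabulate((a[ok] - 1L) * L + b[ok], nbins = L * L)
    C <- matrix(counts, L, L, byrow = TRUE)
    P <- C + t(C)
    P <- P / sum(P)
    acc <- acc + glcm_from_matrix(P)
    n_used <- n_used + 1
  }
  if (n_used == 0) return(rep(NA_real_, 24))
  acc / n_used
}

glcm_from_matrix <- function(P) {
  L <- nrow(P)
  i <- matrix(seq_len(L), L, L)
  j <- t(i)
  px <- rowSums(P)                       # == colSums by symmetry
  present <- which(px > 0)
  Ng <- length(present)
  mu <- sum(seq_len(L) * px)
  sig2 <- sum((seq_len(L) - mu)^2 * px)

  # diagonal / cross-diagonal distributions
  kd <- 0:(L - 1)
  pxmy <- vapply(kd, function(k) sum(P[abs(i - j) == k]), numeric(1))
  ks <- 2:(2 * L)
  pxpy <- vapply(ks, function(k) sum(P[(i + j) == k]), numeric(1))

  autoc <- sum(i * j * P)
  joint_avg <- mu
  cl <- i + j - 2 * mu
  cluster_prom <- sum(cl^4 * P)
  cluster_shade <- sum(cl^3 * P)
  cluster_tend <- sum(cl^2 * P)
  contrast <- sum((i - j)^2 * P)
  correlation <- if (sig2 > 0) (autoc - mu^2) / sig2 else 1
  da <- sum(kd * pxmy)
  dentropy <- -sum(pxmy[pxmy > 0] * log2(pxmy[pxmy > 0]))
  dvar <- sum((kd - da)^2 * pxmy)
  id <- sum(pxmy / (1 + kd))
  idm <- sum(pxmy / (1 + kd^2))
  idmn <- sum(pxmy / (1 + (kd / Ng)^2))
  idn <- sum(pxmy / (1 + kd / Ng))
  invvar <- if (L > 1) sum(pxmy[-1] / kd[-1]^2) else 0
  jenergy <- sum(P^2)
  jentropy <- -sum(P[P > 0] * log2(P[P > 0]))

  pxpy_outer <- outer(px, px)
  hxy1 <- -sum(P[P > 0] * log2(pxpy_outer[P > 0]))
  hxy2 <- -sum(pxpy_outer[pxpy_outer > 0] *
                 log2(pxpy_outer[pxpy_outer > 0]))
  hx <- -sum(px[px > 0] * log2(px[px > 0]))
  imc1 <- if (hx > 0) (jentropy - hxy1) / hx else 0
  imc2 <- sqrt(pmax(1 - exp(-2 * (hxy2 - jentropy)), 0))

  mcc <- if (Ng <= 1) 1 else {
    # Q[a,b] = sum_k P[a,k] P[b,k] / (px[a] px[k])
    Pp <- P[present, present, drop = FALSE]
    pxp <- px[present]
    W <- sweep(Pp, 2, pxp, "/")
    Q <- sweep(Pp %*% t(W), 1, pxp, "/")
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    sqrt(pmax(ev[2], 0))
  }

  maxp <- max(P)
  sum_avg <- sum(ks * pxpy)
  sum_entropy <- -sum(pxpy[pxpy > 0] * log2(pxpy[pxpy > 0]))
  sum_squares <- sig2

  c(autoc, joint_avg, cluster_prom, cluster_shade, cluster_tend, contrast,
    correlation, da, dentropy, dvar, id, idm, idmn, idn, imc1, imc2, invvar,
    jenergy, jentropy, mcc, maxp, sum_avg, sum_entropy, sum_squares)
}

# ---- GLRLM ------------------------------------------------------------------

glrlm_features <- function(gl) {
  dims <- dim(gl)
  idx <- which(!is.na(gl), arr.ind = TRUE)
  g <- gl[!is.na(gl)]
  Np <- length(g)
  L <- max(g)
  dirs <- unique_directions_3d()
  acc <- numeric(16)
  n_used <- 0
  for (di in seq_len(nrow(dirs))) {
    d <- dirs[di, ]
    a0 <- which(d != 0)[1]
    t <- idx[, a0] * sign(d[a0])
    key1 <- idx[, 1] - t * d[1]
    key2 <- idx[, 2] - t * d[2]
    key3 <- idx[, 3] - t * d[3]
    ord <- order(key1, key2, key3, t)
    ko1 <- key1[ord]; ko2 <- key2[ord]; ko3 <- key3[ord]
    to <- t[ord]; go <- g[ord]
    new_run <- c(TRUE,
                 ko1[-1] != ko1[-Np] | ko2[-1] != ko2[-Np] |
                   ko3[-1] != ko3[-Np] | to[-1] != to[-Np] + 1 |
                   go[-1] != go[-Np])
    run_id <- cumsum(new_run)
    run_len <- tabulate(run_id)
    run_gray <- go[new_run]
    Jmax <- max(run_len)
    Pm <- matrix(0, L, Jmax)
    tab <- tabulate((run_gray - 1L) * Jmax + run_len, nbins = L * Jmax)
    Pm <- matrix(tab, L, Jmax, byrow = TRUE)
    acc <- acc + rl_features_from_matrix(Pm, Np)
    n_used <- n_used + 1
  }
  acc / n_used
}

# shared run-length-style features: P[i, j] with i = gray level, j = run
# length (GLRLM) or zone size (GLSZM); Np = voxel count
rl_features_from_matrix <- function(P, Np) {
  Nr <- sum(P)
  L <- nrow(P); J <- ncol(P)
  iv <- seq_len(L); jv <- seq_len(J)
  ri <- rowSums(P); cj <- colSums(P)
  p <- P / Nr
  mu_i <- sum(iv * rowSums(p))
  mu_j <- sum(jv * colSums(p))
  pr <- p[p > 0]
  c(
    SRE = sum(cj / jv^2) / Nr,
    LRE = sum(cj * jv^2) / Nr,
    GLN = sum(ri^2) / Nr,
    GLNN = sum(ri^2) / Nr^2,
    RLN = sum(cj^2) / Nr,
    RLNN = sum(cj^2) / Nr^2,
    RP = Nr / Np,
    GLV = sum((iv - mu_i)^2 * rowSums(p)),
    RV = sum((jv - mu_j)^2 * colSums(p)),
    RE = -sum(pr * log2(pr)),
    LGLRE = sum(ri / iv^2) / Nr,
    HGLRE = sum(ri * iv^2) / Nr,
    SRLGLE = sum(P / outer(iv^2, jv^2)) / Nr,
    SRHGLE = sum(P * outer(iv^2, 1 / jv^2)) / Nr,
    LRLGLE = sum(P * outer(1 / iv^2, jv^2)) / Nr,
    LRHGLE = sum(P * outer(iv^2, jv^2)) / Nr
  )
}

# ---- GLSZM ------------------------------------------------------------------

glszm_features <- function(gl) {
  dims <- dim(gl)
  in_mask <- !is.na(gl)
  n <- sum(in_mask)
  id <- array(NA_integer_, dims)
  id[in_mask] <- seq_len(n)
  g <- gl[in_mask]
  L <- max(g)

  edges <- list()
  dirs <- unique_directions_3d()
  for (di in seq_len(nrow(dirs))) {
    sh_id <- shifted_blocks(id, dirs[di, ])
    sh_gl <- shifted_blocks(gl, dirs[di, ])
    ok <- !is.na(sh_id$centre) & !is.na(sh_id$neighbour) &
      sh_gl$centre == sh_gl$neighbour
    if (any(ok)) {
      edges[[length(edges) + 1]] <-
        rbind(sh_id$centre[ok], sh_id$neighbour[ok])
    }
  }
  graph <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(edges)) {
    graph <- igraph::add_edges(graph, as.vector(do.call(cbind, edges)))
  }
  comp <- igraph::components(graph)
  zone_size <- comp$csize
  zone_gray <- g[match(seq_len(comp$no), comp$membership)]

  Smax <- max(zone_size)
  tab <- tabulate((zone_gray - 1L) * Smax + zone_size, nbins = L * Smax)
  P <- matrix(tab, L, Smax, byrow = TRUE)

  f <- rl_features_from_matrix(P, n)
  # same formula family; rename semantics: runs -> zones
  unname(f[c("SRE", "LRE", "GLN", "GLNN", "RLN", "RLNN", "RP", "GLV", "RV",
             "RE", "LGLRE", "HGLRE", "SRLGLE", "SRHGLE", "LRLGLE", "LRHGLE")])
}

# ---- neighbourhood accumulators (shared by NGTDM / GLDM) -------------------

neighbour_stats <- function(gl) {
  dims <- dim(gl)
  nsum <- array(0, dims)
  ncnt <- array(0L, dims)
  neq <- array(0L, dims)
  dirs <- unique_directions_3d()
  for (di in seq_len(nrow(dirs))) {
    d <- dirs[di, ]
    b <- block_ranges(dims, d)
    a <- gl[b$centre[[1]], b$centre[[2]], b$centre[[3]], drop = FALSE]
    nb <- gl[b$neighbour[[1]], b$neighbour[[2]], b$neighbour[[3]], drop = FALSE]
    ok <- !is.na(a) & !is.na(nb)
    eq <- ok & (a == nb)
    add_block <- function(arr, ranges, inc) {
      arr[ranges[[1]], ranges[[2]], ranges[[3]]] <-
        arr[ranges[[1]], ranges[[2]], ranges[[3]], drop = FALSE] + inc
      arr
    }
    nb0 <- nb; nb0[!ok] <- 0L
    a0 <- a; a0[!ok] <- 0L
    nsum <- add_block(nsum, b$centre, nb0)
    nsum <- add_block(nsum, b$neighbour, a0)
    ncnt <- add_block(ncnt, b$centre, as.integer(ok))
    ncnt <- add_block(ncnt, b$neighbour, as.integer(ok))
    neq <- add_block(neq, b$centre, as.integer(eq))
    neq <- add_block(neq, b$neighbour, as.integer(eq))
  }
  list(nsum = nsum, ncnt = ncnt, neq = neq)
}

# ---- NGTDM ------------------------------------------------------------------

ngtdm_features <- function(gl) {
  st <- neighbour_stats(gl)
  in_mask <- !is.na(gl)
  valid <- in_mask & st$ncnt > 0
  g <- gl[valid]
  abar <- st$nsum[valid] / st$ncnt[valid]
  Nvp <- length(g)
  L <- max(gl, na.rm = TRUE)
  n_i <- tabulate(g, nbins = L)
  s_i <- vapply(seq_len(L), function(l) sum(abs(l - abar)[g == l]), numeric(1))
  p_i <- n_i / Nvp
  pres <- which(n_i > 0)
  Ngp <- length(pres)

  coarse_den <- sum(p_i * s_i)
  coarseness <- if (coarse_den > 0) 1 / coarse_den else 1e6

  contrast <- if (Ngp > 1) {
    pij <- outer(p_i[pres], p_i[pres])
    dij2 <- outer(pres, pres, "-")^2
    sum(pij * dij2) / (Ngp * (Ngp - 1)) * sum(s_i) / Nvp
  } else 0

  # denominator runs over all ordered pairs of present levels
  ipi <- pres * p_i[pres]
  busy_den <- sum(abs(outer(ipi, ipi, "-")))
  busyness <- if (busy_den > 0) coarse_den / busy_den else 0

  complexity <- if (Ngp > 0) {
    num <- 0
    for (ii in pres) for (jj in pres) {
      num <- num + abs(ii - jj) * (p_i[ii] * s_i[ii] + p_i[jj] * s_i[jj]) /
        (p_i[ii] + p_i[jj])
    }
    num / Nvp
  } else 0

  strength_num <- 0
  for (ii in pres) for (jj in pres) {
    strength_num <- strength_num + (p_i[ii] + p_i[jj]) * (ii - jj)^2
  }
  strength <- if (sum(s_i) > 0) strength_num / sum(s_i) else 0

  c(coarseness, contrast, busyness, complexity, strength)
}

# ---- GLDM -------------------------------------------------------------------

gldm_features <- function(gl) {
  st <- neighbour_stats(gl)
  in_mask <- !is.na(gl)
  g <- gl[in_mask]
  dep <- st$neq[in_mask] + 1L   # dependence size includes the centre voxel
  L <- max(g)
  J <- max(dep)
  tab <- tabulate((g - 1L) * J + dep, nbins = L * J)
  P <- matrix(tab, L, J, byrow = TRUE)
  Nz <- sum(P)                  # every masked voxel contributes one entry
  iv <- seq_len(L); jv <- seq_len(J)
  ri <- rowSums(P); cj <- colSums(P)
  p <- P / Nz
  mu_i <- sum(iv * rowSums(p))
  mu_j <- sum(jv * colSums(p))
  pr <- p[p > 0]
  c(
    SDE = sum(cj / jv^2) / Nz,
    LDE = sum(cj * jv^2) / Nz,
    GLN = sum(ri^2) / Nz,
    DN = sum(cj^2) / Nz,
    DNN = sum(cj^2) / Nz^2,
    GLV = sum((iv - mu_i)^2 * rowSums(p)),
    DV = sum((jv - mu_j)^2 * colSums(p)),
    DE = -sum(pr * log2(pr)),
    LGLE = sum(ri / iv^2) / Nz,
    HGLE = sum(ri * iv^2) / Nz,
    SDLGLE = sum(P / outer(iv^2, jv^2)) / Nz,
    SDHGLE = sum(P * outer(iv^2, 1 / jv^2)) / Nz,
    LDLGLE = sum(P * outer(1 / iv^2, jv^2)) / Nz,
    LDHGLE = sum(P * outer(iv^2, jv^2)) / Nz
  )
}
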