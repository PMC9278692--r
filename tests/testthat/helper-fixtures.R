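# Shared fixtures and independent brute-force oracles used across tests.

# small, fast phantom: 16x24x24 voxels, 4 mm isotropic
tiny_spec <- function(seed = 1L) {
  phantom_spec(
    grid_shape = c(16, 24, 24), spacing = c(4, 4, 4),
    body_semiaxes = c(40, 44),
    organs = list(
      phantom_organ("liver", "ellipsoid", c(0, 5, 12), c(20, 18, 14), 54, 3),
      phantom_organ("spinal_canal", "cylinder", c(0, 24, 0), c(Inf, 8, 8), 22, 6),
      phantom_organ("ptv", "sphere", c(0, 0, 14), 8, 60, 5)),
    seed = seed)
}

# finer in-plane grid (2 mm) so that millimetre-scale contour displacements
# are resolvable by nearest-neighbour mask warping
fine_spec <- function(seed = 1L) {
  phantom_spec(
    grid_shape = c(16, 44, 44), spacing = c(3, 2, 2),
    body_semiaxes = c(40, 40),
    organs = list(
      phantom_organ("liver", "ellipsoid", c(0, 5, 10), c(18, 16, 12), 54, 3),
      phantom_organ("spinal_canal", "cylinder", c(0, 24, 0), c(Inf, 7, 7), 22, 6)),
    seed = seed)
}

vol_from <- function(data, spacing = c(1, 1, 1), origin = NULL) {
  if (is.matrix(data)) data <- array(data, dim = c(1, dim(data)))
  image_volume(data, spacing, origin)
}

mask_from <- function(idx, dim, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                      name = "m") {
  m <- array(FALSE, dim)
  m[idx] <- TRUE
  structure(list(mask = m, spacing = spacing, origin = origin, name = name),
            class = "structure_mask")
}

dose_from <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                      prescription = 50) {
  if (is.matrix(data)) data <- array(data, dim = c(1, dim(data)))
  structure(list(data = data, spacing = spacing, origin = origin,
                 prescription = prescription, fractions = 5, scale = 1),
            class = c("dose_grid", "image_volume"))
}

# ---- brute-force oracles ----------------------------------------------------

# directed/symmetric Hausdorff by exhaustive pairwise distances over surface
# voxel centres (no nearest-neighbour shortcuts)
brute_hausdorff <- function(X, Y, mode = "max") {
  ns <- asNamespace("adaptsct")
  A <- ns$surface_points(X$mask, X$spacing, X$origin)
  B <- ns$surface_points(Y$mask, Y$spacing, Y$origin)
  D <- matrix(0, nrow(A), nrow(B))
  for (i in seq_len(nrow(A)))
    for (j in seq_len(nrow(B)))
      D[i, j] <- sqrt(sum((A[i, ] - B[j, ])^2))
  dab <- apply(D, 1, min); dba <- apply(D, 2, min)
  if (mode == "max") max(max(dab), max(dba)) else (mean(dab) + mean(dba)) / 2
}

# exhaustive gamma: for every reference voxel above threshold, minimise the
# Low combined criterion over the FULL interpolated candidate lattice (the
# same dta/3 refinement the implementation uses, but with no search-radius
# or pruning shortcuts)
brute_gamma <- function(ref, ev, spacing, dd_abs, dta, thr_abs, cap,
                        valid = NULL) {
  ns <- asNamespace("adaptsct")
  d <- dim(ref)
  kfac <- pmax(1L, as.integer(ceiling(spacing / (dta / 3))))
  if (d[1] == 1L) kfac[1] <- 1L
  nd <- (d - 1L) * kfac + 1L
  sub_sp <- spacing / kfac
  lattice <- ns$.resample_tri(ev, c(0, 0, 0), spacing, as.integer(nd),
                              c(0, 0, 0), sub_sp)$values
  lz <- (seq_len(nd[1]) - 1) * sub_sp[1]
  ly <- (seq_len(nd[2]) - 1) * sub_sp[2]
  lx <- (seq_len(nd[3]) - 1) * sub_sp[3]
  LZ <- array(rep(lz, times = nd[2] * nd[3]), dim = nd)
  LY <- array(rep(rep(ly, each = nd[1]), times = nd[3]), dim = nd)
  LX <- array(rep(lx, each = nd[1] * nd[2]), dim = nd)
  if (is.null(valid)) valid <- array(TRUE, d)
  g <- array(NA_real_, d)
  for (iz in seq_len(d[1])) for (iy in seq_len(d[2])) for (ix in seq_len(d[3])) {
    if (!valid[iz, iy, ix] || ref[iz, iy, ix] < thr_abs) next
    z0 <- (iz - 1) * spacing[1]; y0 <- (iy - 1) * spacing[2]
    x0 <- (ix - 1) * spacing[3]
    G2 <- ((LZ - z0)^2 + (LY - y0)^2 + (LX - x0)^2) / dta^2 +
      (lattice - ref[iz, iy, ix])^2 / dd_abs^2
    g[iz, iy, ix] <- min(sqrt(min(G2)), cap)
  }
  g
}

# smooth random 3D dose field (sum of separable low-frequency sinusoids)
smooth_dose_field <- function(dims, seed, base = 10) {
  set.seed(seed)
  g <- function(n) sin(2 * pi * runif(1, 0.3, 1.1) * (seq_len(n) - 1) / n +
                         runif(1, 0, 2 * pi))
  comp <- function() {
    yx <- outer(g(dims[2]), g(dims[3]))
    zc <- g(dims[1])
    array(rep(zc, times = dims[2] * dims[3]), dims) *
      aperm(array(yx, c(dims[2], dims[3], dims[1])), c(3, 1, 2))
  }
  base + comp() + 0.7 * comp()
}
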