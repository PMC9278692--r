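# Plan-comparison statistics: cumulative DVHs, dose statistics, 2D/3D gamma
# per the Low distance-to-agreement formulation, histograms, and dose-level
# contour extraction.

#' Cumulative dose-volume histogram
#'
#' Fraction of structure voxels receiving at least each dose level; starts
#' at 1.0 at dose 0 and is non-increasing.
#'
#' @param dose a `dose_grid` (or [image_volume] of dose).
#' @param mask non-empty `structure_mask` or logical array on the dose grid.
#' @param bin_width dose-axis step in Gy.
#' @return data.frame with `dose` (Gy) and `volume` (fraction), class
#'   `dvh_curve`.
#' @export
compute_dvh <- function(dose, mask, bin_width = 0.5) {
  m <- as_mask_array(mask)
  if (!identical(dim(m), dim(dose$data))) stop("dose and mask must share a grid")
  v <- dose$data[m]
  if (length(v) == 0) stop("empty mask")
  edges <- seq(0, max(v) + bin_width, by = bin_width)
  vol <- vapply(edges, function(e) mean(v >= e), 0)
  structure(data.frame(dose = edges, volume = vol),
            class = c("dvh_curve", "data.frame"))
}

#' DVH statistics as percent of prescription
#'
#' @inheritParams compute_dvh
#' @param prescription prescription dose in Gy (> 0).
#' @return list: `min_pct`, `mean_pct`, `max_pct` (voxel doses as % of
#'   prescription) and `v100_pct` (% of the structure receiving at least
#'   the prescription dose).
#' @export
dvh_stats <- function(dose, mask, prescription = NULL) {
  prescription <- prescription %||% dose$prescription
  if (is.null(prescription) || prescription <= 0)
    stop("prescription must be > 0")
  m <- as_mask_array(mask)
  v <- dose$data[m]
  if (length(v) == 0) stop("empty mask")
  list(min_pct = 100 * min(v) / prescription,
       mean_pct = 100 * mean(v) / prescription,
       max_pct = 100 * max(v) / prescription,
       v100_pct = 100 * mean(v >= prescription))
}

#' Gamma-analysis parameters
#'
#' @param dd dose-difference criterion, percent of the normalization dose.
#' @param dta distance-to-agreement criterion, mm.
#' @param threshold low-dose threshold, percent of normalization; reference
#'   voxels below it are excluded from the analysis.
#' @param norm normalization dose in Gy; default = max of the reference
#'   (global gamma).
#' @param search search radius in multiples of `dta`.
#' @param cap upper bound applied to gamma values.
#' @return object of class `gamma_params`.
#' @export
gamma_params <- function(dd = 3, dta = 2, threshold = 10, norm = NULL,
                         search = 3, cap = 2) {
  if (dd <= 0 || dta <= 0) stop("dd and dta must be > 0")
  if (cap < 1) stop("cap must be >= 1")
  structure(list(dd = dd, dta = dta, threshold = threshold, norm = norm,
                 search = search, cap = cap),
            class = "gamma_params")
}

extract_plane <- function(vol, plane, index = NULL) {
  ax <- switch(plane, axial = 1L, coronal = 2L, sagittal = 3L)
  n <- dim(vol$data)[ax]
  if (is.null(index))  # plane through the world origin (isocenter)
    index <- which.min(abs(vol$origin[ax] + (seq_len(n) - 1) * vol$spacing[ax]))
  keep <- setdiff(1:3, ax)
  sl <- switch(plane, axial = vol$data[index, , ],
               coronal = vol$data[, index, ], sagittal = vol$data[, , index])
  arr <- array(sl, dim = c(1, dim(sl)))
  list(vol = structure(list(data = arr,
                            spacing = c(1, vol$spacing[keep]),
                            origin = c(0, vol$origin[keep]),
                            prescription = vol$prescription,
                            fractions = vol$fractions),
                       class = class(vol)),
       index = index, axis = ax)
}

#' Gamma map between a reference and an evaluated dose distribution
#'
#' For every reference voxel above the low-dose threshold, the gamma index
#' is the minimum over nearby evaluated positions of
#' `sqrt(dist^2/dta^2 + doseDiff^2/dd^2)`, the evaluated dose being
#' trilinearly interpolated on a sub-grid of spacing <= dta/3; values are
#' capped. Grids must already share a geometry (see [resample_dose()]);
#' voxels marked invalid by resampling are excluded from numerator and
#' denominator of the pass rate.
#'
#' @param reference,evaluated `dose_grid` objects on one grid.
#' @param params a [gamma_params()].
#' @param dims "3D", or "2D" for a single orthogonal plane through the
#'   isocenter.
#' @param plane for 2D: "axial", "coronal" or "sagittal".
#' @param index optional explicit slice index for 2D.
#' @return object of class `gamma_map`: capped per-voxel `gamma` (NA below
#'   threshold/invalid), `pass_rate` (%), `n_evaluated`, `norm`, `params`.
#' @export
gamma_map <- function(reference, evaluated, params = gamma_params(),
                      dims = c("3D", "2D"), plane = "axial", index = NULL) {
  dims <- match.arg(dims)
  stop_if_grid_mismatch(reference, evaluated, "dose grids")
  valid <- attr(evaluated, "valid") %||% array(TRUE, dim(reference$data))
  if (dims == "2D") {
    pr <- extract_plane(reference, plane, index)
    pe <- extract_plane(evaluated, plane, pr$index)
    vv <- extract_plane(list(data = array(as.numeric(valid), dim(valid)),
                             spacing = reference$spacing,
                             origin = reference$origin), plane, pr$index)
    reference <- pr$vol; evaluated <- pe$vol
    valid <- vv$vol$data > 0.5
  }
  norm <- params$norm %||% max(reference$data)
  if (norm <= 0) stop("normalization dose must be > 0")
  dd_abs <- params$dd / 100 * norm
  thr_abs <- params$threshold / 100 * norm
  kfac <- pmax(1L, as.integer(ceiling(reference$spacing / (params$dta / 3))))
  if (dim(reference$data)[1] == 1L) kfac[1] <- 1L
  g <- .gamma_search(reference$data, evaluated$data,
                     array(valid, dim(reference$data)), reference$spacing,
                     dd_abs, params$dta, thr_abs,
                     params$search * params$dta, params$cap, kfac)
  ev <- !is.na(g)
  structure(list(gamma = g, pass_rate = 100 * mean(g[ev] <= 1),
                 n_evaluated = sum(ev), norm = norm, params = params,
                 dims = dims, spacing = reference$spacing,
                 origin = reference$origin),
            class = "gamma_map")
}

#' @export
print.gamma_map <- function(x, ...) {
  cat(sprintf("<gamma_map> %s, %d evaluated voxels, pass rate %.2f%% (gamma <= 1)\n",
              x$dims, x$n_evaluated, x$pass_rate))
  cat(sprintf("  criteria %g%%/%g mm, threshold %g%%, norm %.3g Gy, cap %g\n",
              x$params$dd, x$params$dta, x$params$threshold, x$norm,
              x$params$cap))
  invisible(x)
}

#' Resample a dose grid onto another grid geometry
#'
#' Trilinear resampling; target voxels outside the source extent are marked
#' invalid (attribute `valid`) and excluded from gamma analysis.
#'
#' @param dose a `dose_grid`.
#' @param target an [image_volume]/`dose_grid` supplying the target geometry.
#' @return a `dose_grid` on the target grid.
#' @export
resample_dose <- function(dose, target) {
  td <- dim(target$data)
  src_lo <- dose$origin; src_hi <- dose$origin + (dim(dose$data) - 1) * dose$spacing
  tgt_lo <- target$origin; tgt_hi <- target$origin + (td - 1) * target$spacing
  if (any(tgt_hi < src_lo) || any(tgt_lo > src_hi))
    stop("dose and target grids do not overlap")
  rs <- .resample_tri(dose$data, dose$origin, dose$spacing,
                      as.integer(td), target$origin, target$spacing)
  out <- structure(list(data = rs$values, spacing = target$spacing,
                        origin = target$origin,
                        prescription = dose$prescription,
                        fractions = dose$fractions, scale = dose$scale),
                   class = c("dose_grid", "image_volume"))
  if (!all(rs$valid)) attr(out, "valid") <- rs$valid
  out
}

#' Histogram of gamma values
#' @param g a [gamma_map()] result.
#' @param bins bin count over `[0, cap]` (256 in the assessment this mirrors).
#' @return data.frame `bin_left`, `bin_right`, `count`; counts sum to the
#'   evaluated-voxel count.
#' @export
gamma_histogram <- function(g, bins = 256) {
  v <- g$gamma[!is.na(g$gamma)]
  cap <- g$params$cap
  edges <- seq(0, cap, length.out = bins + 1)
  idx <- pmin(findInterval(v, edges, rightmost.closed = TRUE), bins)
  idx <- pmax(idx, 1L)
  data.frame(bin_left = edges[-(bins + 1)], bin_right = edges[-1],
             count = tabulate(idx, nbins = bins))
}

#' Percent dose-difference histogram
#'
#' Per-voxel `100 * (evaluated - reference) / norm` over reference voxels
#' above the low-dose threshold.
#'
#' @param reference,evaluated dose grids on one grid.
#' @param threshold percent of normalization below which voxels are ignored.
#' @param bins histogram bins (1024 in the assessment this mirrors).
#' @param norm normalization dose; default max of reference.
#' @return list: `histogram` data.frame and `mean` percent difference.
#' @export
dose_diff_histogram <- function(reference, evaluated, threshold = 10,
                                bins = 1024, norm = NULL) {
  stop_if_grid_mismatch(reference, evaluated, "dose grids")
  norm <- norm %||% max(reference$data)
  sel <- reference$data >= threshold / 100 * norm
  valid <- attr(evaluated, "valid")
  if (!is.null(valid)) sel <- sel & valid
  dif <- 100 * (evaluated$data[sel] - reference$data[sel]) / norm
  rng <- range(dif)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  edges <- seq(rng[1], rng[2], length.out = bins + 1)
  idx <- pmin(pmax(findInterval(dif, edges, rightmost.closed = TRUE), 1L), bins)
  list(histogram = data.frame(bin_left = edges[-(bins + 1)],
                              bin_right = edges[-1],
                              count = tabulate(idx, nbins = bins)),
       mean = mean(dif))
}

#' Iso-dose contours on an orthogonal plane
#'
#' Marching-squares contour extraction of dose levels for overlay
#' comparison of plans. Levels outside the in-plane dose range return an
#' empty contour set flagged in the result.
#'
#' @param dose a `dose_grid`.
#' @param levels dose levels in Gy.
#' @param plane "axial", "coronal" or "sagittal".
#' @param index optional slice index (default: through the isocenter).
#' @return named list (one element per level) of lists of data.frames with
#'   in-plane world coordinates `u`, `v` (mm); attribute `flagged` names
#'   out-of-range levels.
#' @export
isodose_contours <- function(dose, levels, plane = "axial", index = NULL) {
  p <- extract_plane(dose, plane, index)
  sl <- matrix(p$vol$data[1, , ], dim(p$vol$data)[2], dim(p$vol$data)[3])
  u <- p$vol$origin[2] + (seq_len(nrow(sl)) - 1) * p$vol$spacing[2]
  v <- p$vol$origin[3] + (seq_len(ncol(sl)) - 1) * p$vol$spacing[3]
  out <- list(); flagged <- character()
  for (lv in levels) {
    key <- as.character(lv)
    if (lv <= min(sl) || lv >= max(sl)) {
      out[[key]] <- list()
      flagged <- c(flagged, key)
      next
    }
    cl <- grDevices::contourLines(u, v, sl, levels = lv)
    out[[key]] <- lapply(cl, function(cc) data.frame(u = cc$x, v = cc$y))
  }
  attr(out, "flagged") <- flagged
  out
}

#' Maximum in-plane divergence between matched iso-dose contours
#'
#' For each level present in both sets, the symmetric maximum over contour
#' points of the distance to the nearest point of the other plan's contour.
#'
#' @param a,b results of [isodose_contours()] at the same levels.
#' @return named numeric vector (mm per level; NA when either side is empty).
#' @export
isodose_divergence <- function(a, b) {
  lev <- intersect(names(a), names(b))
  out <- setNames(rep(NA_real_, length(lev)), lev)
  for (k in lev) {
    pa <- do.call(rbind, a[[k]]); pb <- do.call(rbind, b[[k]])
    if (is.null(pa) || is.null(pb) || nrow(pa) == 0 || nrow(pb) == 0) next
    A <- as.matrix(pa); B <- as.matrix(pb)
    out[k] <- max(max(directed_min_dists(A, B)), max(directed_min_dists(B, A)))
  }
  out
}
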