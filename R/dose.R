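# Stand-in dose engine. This is explicitly NOT a clinical dose algorithm:
# it is a deterministic divergent-beam ray-trace that deposits
# weight * exp(-mu * radiological_depth) inside a rectangular field, summed
# over beams. It exists to map HU/ED errors into dose errors smoothly and
# reproducibly; all dose numbers it emits are stand-in values, without
# absolute Gy calibration claims.

#' Define a beam
#'
#' @param gantry gantry angle in degrees; the source rotates about the
#'   patient z axis at distance `sad` from the isocenter (0 deg enters
#'   anteriorly, i.e. from -y).
#' @param iso isocenter (z, y, x) world mm.
#' @param width,height field width (in-plane) and height (along z) in mm,
#'   defined at the isocenter plane.
#' @param weight monitor-unit-like scalar (>= 0).
#' @param mu effective attenuation coefficient per mm of water-equivalent
#'   depth.
#' @param sad source-axis distance, mm.
#' @return object of class `beam`.
#' @export
beam <- function(gantry, iso = c(0, 0, 0), width = 100, height = 80,
                 weight = 1, mu = 0.005, sad = 1000) {
  if (weight < 0) stop("beam weight must be >= 0")
  if (mu <= 0) stop("mu must be > 0")
  th <- gantry * pi / 180
  source <- iso + sad * c(0, -cos(th), sin(th))
  structure(list(gantry = gantry, iso = as.numeric(iso), width = width,
                 height = height, weight = weight, mu = mu, sad = sad,
                 source = source),
            class = "beam")
}

#' Approximate a VMAT partial arc by equally spaced static beams
#' @param from,to arc limits in gantry degrees.
#' @param n number of static beams.
#' @param ... passed to [beam()]; the total `weight` is split across beams.
#' @param weight total arc weight.
#' @export
beam_arc <- function(from, to, n = 12, weight = 1, ...) {
  ang <- seq(from, to, length.out = n)
  lapply(ang, function(a) beam(a, weight = weight / n, ...))
}

default_step <- function(vol) 0.5 * min(vol$spacing)

#' Water-equivalent (radiological) depth along rays
#'
#' Line integral of relative electron density from a source point to each
#' target, with fixed-step sampling (default half the smallest voxel
#' spacing) and trilinear ED interpolation; ED outside the volume is 0.
#'
#' @param ed relative-electron-density [image_volume].
#' @param source (z, y, x) world mm, outside the body.
#' @param targets matrix of world points (columns z, y, x), or a vector for
#'   a single point.
#' @param step sampling step in mm.
#' @return mm of water-equivalent depth per target.
#' @export
radiological_depth <- function(ed, source, targets, step = NULL) {
  if (is.null(dim(targets))) targets <- matrix(targets, nrow = 1)
  .radio_depth(ed$data, ed$origin, ed$spacing, as.numeric(source),
               as.matrix(targets), step %||% default_step(ed))
}

#' Compute a stand-in dose distribution
#'
#' Per beam, dose at a voxel is `weight * exp(-mu * radiological_depth)`
#' inside the divergent geometric field and 0 outside, summed over beams.
#' If a PTV mask is supplied the total is scaled so the mean PTV dose
#' equals the prescription (otherwise doses stay in beam-weight units).
#'
#' @param ed relative-electron-density [image_volume].
#' @param beams list of [beam()] objects (>= 1).
#' @param prescription prescription dose in Gy.
#' @param fractions fraction count (metadata).
#' @param ptv optional PTV `structure_mask` (or logical array) used for
#'   prescription scaling; must be non-empty.
#' @param scale explicit multiplicative factor applied instead of PTV
#'   scaling (used to impose one plan's monitor units on another ED map).
#' @param step ray-sampling step, mm.
#' @return object of class `dose_grid` (an [image_volume] plus
#'   `prescription`, `fractions` and the applied `scale`).
#' @export
compute_dose <- function(ed, beams, prescription = 50, fractions = 5,
                         ptv = NULL, scale = NULL, step = NULL) {
  if (inherits(beams, "beam")) beams <- list(beams)
  if (length(beams) < 1) stop("need at least one beam")
  step <- step %||% default_step(ed)
  total <- array(0, dim = dim(ed$data))
  for (b in beams) {
    total <- total + .beam_dose(ed$data, ed$origin, ed$spacing, b$source,
                                b$iso, b$width / 2, b$height / 2, b$weight,
                                b$mu, step)
  }
  if (is.null(scale)) {
    scale <- 1
    if (!is.null(ptv)) {
      pm <- as_mask_array(ptv)
      if (sum(pm) == 0) stop("PTV mask is empty; cannot scale to prescription")
      mptv <- mean(total[pm])
      if (mptv <= 0) stop("no dose reaches the PTV; check beam geometry")
      scale <- prescription / mptv
    }
  }
  structure(list(data = total * scale, spacing = ed$spacing,
                 origin = ed$origin, prescription = prescription,
                 fractions = fractions, scale = scale),
            class = c("dose_grid", "image_volume"))
}

#' Structure dose statistics for several plans, with pairwise deviations
#'
#' For each plan and structure: min / mean / max voxel dose as percent of
#' prescription. For each plan pair and structure: the mean percent-of-
#' prescription dose difference. Mirrors the per-structure dose-statistics
#' layout of clinical sCT assessments.
#'
#' @param doses named list of `dose_grid` objects on one grid (e.g.
#'   `list(ct = ..., cbct = ..., sct = ...)`).
#' @param masks [structure_set] providing the structures.
#' @param structures structure names (default `ptv` and `liver` if present,
#'   else all but body).
#' @return list with data frames `stats` and `pairwise`.
#' @export
dose_sensitivity_report <- function(doses, masks, structures = NULL) {
  if (is.null(names(doses)) || length(doses) < 2)
    stop("`doses` must be a named list of at least two dose grids")
  ref <- doses[[1]]
  for (d in doses) stop_if_grid_mismatch(ref, d, "dose grids")
  structures <- structures %||%
    intersect(c("ptv", "liver"), names(masks$masks))
  if (length(structures) == 0)
    structures <- setdiff(names(masks$masks), c("body", "air_pockets"))
  rx <- ref$prescription
  stats <- list(); pw <- list()
  for (s in structures) {
    m <- masks$masks[[s]]
    if (is.null(m) || sum(m) == 0) stop(sprintf("empty structure '%s'", s))
    vals <- lapply(doses, function(d) d$data[m])
    for (nm in names(doses))
      stats[[length(stats) + 1]] <- data.frame(
        plan = nm, structure = s,
        min_pct = 100 * min(vals[[nm]]) / rx,
        mean_pct = 100 * mean(vals[[nm]]) / rx,
        max_pct = 100 * max(vals[[nm]]) / rx)
    cmb <- utils::combn(names(doses), 2)
    for (k in seq_len(ncol(cmb)))
      pw[[length(pw) + 1]] <- data.frame(
        plan_a = cmb[1, k], plan_b = cmb[2, k], structure = s,
        mean_diff_pct = 100 * mean(vals[[cmb[1, k]]] - vals[[cmb[2, k]]]) / rx)
  }
  list(stats = do.call(rbind, stats), pairwise = do.call(rbind, pw))
}
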