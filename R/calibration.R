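# HU -> relative electron density conversion via piecewise-linear
# calibration curves. Ships the Catphan-504 OBI measurement table and a
# generic CT-simulator-style default (synthetic, documented).

#' Build an HU / relative-electron-density calibration curve
#'
#' @param rows data.frame with columns `material`, `hu`, `ed` (relative
#'   electron density, water = 1) and optionally `mass_density` (g/cm^3).
#'   Rows are sorted by HU; duplicate HU values are rejected.
#' @param label curve label.
#' @return object of class `calibration_curve`.
#' @export
build_curve <- function(rows, label = "calibration") {
  need <- c("material", "hu", "ed")
  if (!all(need %in% names(rows))) stop("rows need material, hu, ed columns")
  if (nrow(rows) < 2) stop("a calibration curve needs at least 2 knots")
  rows <- rows[order(rows$hu), , drop = FALSE]
  if (anyDuplicated(rows$hu)) stop("duplicate HU knots are not allowed")
  if (any(rows$ed < 0)) stop("relative electron density must be >= 0")
  if (is.null(rows$mass_density)) rows$mass_density <- NA_real_
  rownames(rows) <- NULL
  structure(list(knots = rows, label = label), class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> '%s', %d knots, HU [%g, %g]\n",
              x$label, nrow(x$knots), min(x$knots$hu), max(x$knots$hu)))
  print(x$knots)
  invisible(x)
}

#' Convert HU values to relative electron density
#'
#' Piecewise-linear interpolation between knots, clamped to the end knot
#' values outside the knot range. Knots are reproduced exactly.
#'
#' @param curve a [build_curve()] result.
#' @param hu numeric HU value(s).
#' @return relative electron density (dimensionless, water = 1).
#' @export
hu_to_density <- function(curve, hu) {
  stopifnot(inherits(curve, "calibration_curve"))
  approx(curve$knots$hu, curve$knots$ed, xout = hu, method = "linear",
         rule = 2)$y
}

#' Voxelwise HU to electron-density map
#' @param vol an [image_volume] in HU.
#' @param curve a calibration curve.
#' @return an [image_volume] of relative electron density, same grid.
#' @export
density_map <- function(vol, curve) {
  ed <- array(hu_to_density(curve, as.numeric(vol$data)), dim = dim(vol$data))
  image_volume(ed, vol$spacing, vol$origin)
}

#' Bundled calibration curves
#'
#' `obi_catphan504()` is the on-board-imager curve measured on a Catphan 504
#' phantom with the half-fan filter (six insert materials plus the water
#' anchor and the standard-curve maximum knot). `ct_default()` is a generic
#' CT-simulator-style curve bundled as a documented synthetic stand-in for
#' a clinical planning-CT calibration.
#'
#' @return a `calibration_curve`.
#' @export
obi_catphan504 <- function() {
  read_calibration(system.file("extdata", "obi_catphan504.csv",
                               package = "adaptsct", mustWork = TRUE),
                   label = "OBI Catphan 504 (half-fan)")
}

#' @rdname obi_catphan504
#' @export
ct_default <- function() {
  read_calibration(system.file("extdata", "ct_default.csv",
                               package = "adaptsct", mustWork = TRUE),
                   label = "generic CT simulator (synthetic)")
}

#' Read / write calibration curves as CSV
#' @param path CSV with columns material, hu, ed, mass_density.
#' @param label curve label.
#' @export
read_calibration <- function(path, label = basename(path)) {
  build_curve(utils::read.csv(path, stringsAsFactors = FALSE), label = label)
}

#' @rdname read_calibration
#' @param curve a calibration curve.
#' @export
write_calibration <- function(curve, path) {
  utils::write.csv(curve$knots, path, row.names = FALSE)
  invisible(path)
}
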