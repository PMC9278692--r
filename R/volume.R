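#' 3D image volume with grid metadata
#'
#' The common currency of the whole pipeline: a numeric 3D array of voxel
#' values (HU for CT-like images, relative electron density for ED maps,
#' Gy for dose) together with the grid geometry. Axis order is (z, y, x)
#' throughout the package and the world coordinate of voxel index `i`
#' (1-based, per axis) is `origin + (i - 1) * spacing`, in mm.
#'
#' @param data numeric 3D array, dim (nz, ny, nx).
#' @param spacing numeric length-3, mm per voxel along (z, y, x).
#' @param origin numeric length-3, world mm of the first voxel centre.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(data, spacing, origin = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array (z, y, x)")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be 3 positive values (mm)")
  if (is.null(origin)) origin <- rep(0, 3)
  origin <- as.numeric(origin)
  if (length(origin) != 3L) stop("`origin` must have length 3")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_volume> %d x %d x %d voxels (z,y,x), spacing %s mm, origin %s mm\n",
              d[1], d[2], d[3],
              paste(signif(x$spacing, 4), collapse = "x"),
              paste(signif(x$origin, 4), collapse = ", ")))
  cat(sprintf("  value range [%.6g, %.6g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$data)

is_image_volume <- function(x) inherits(x, "image_volume")

#' Volume of one voxel in mm^3
#' @param vol an `image_volume` or `structure_set`.
#' @return scalar, mm^3.
#' @export
voxel_volume <- function(vol) prod(vol$spacing)

#' World coordinates of the voxel centres along one axis
#' @param vol an `image_volume` or `structure_set`.
#' @param axis 1 (z), 2 (y) or 3 (x).
#' @return numeric vector, mm.
#' @export
axis_coords <- function(vol, axis) {
  n <- dim(vol$data %||% vol$masks[[1]])[axis]
  vol$origin[axis] + (seq_len(n) - 1) * vol$spacing[axis]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

same_grid <- function(a, b, tol = 1e-6) {
  da <- if (is_image_volume(a)) dim(a$data) else dim(a$masks[[1]])
  db <- if (is_image_volume(b)) dim(b$data) else dim(b$masks[[1]])
  identical(da, db) &&
    max(abs(a$spacing - b$spacing)) < tol &&
    max(abs(a$origin - b$origin)) < tol
}

stop_if_grid_mismatch <- function(a, b, what = "inputs") {
  if (!same_grid(a, b)) stop(sprintf("%s must share one grid (dim, spacing, origin)", what))
  invisible(TRUE)
}

#' Named set of binary structure masks on a shared grid
#'
#' Holds the organ / PTV / body masks that annotate an [image_volume].
#' Every mask is a logical array with the same dimensions, spacing and
#' origin as the image it belongs to.
#'
#' @param masks named list of logical 3D arrays.
#' @param spacing,origin grid geometry, as in [image_volume()].
#' @return An object of class `structure_set`.
#' @export
structure_set <- function(masks, spacing, origin = NULL) {
  if (length(masks) == 0 || is.null(names(masks)) || any(names(masks) == ""))
    stop("`masks` must be a non-empty named list")
  d <- dim(masks[[1]])
  for (nm in names(masks)) {
    m <- masks[[nm]]
    if (!is.array(m) || !identical(dim(m), d))
      stop(sprintf("mask '%s' does not share the common grid", nm))
    if (!is.logical(m)) masks[[nm]] <- array(as.logical(m), dim = d)
  }
  if (is.null(origin)) origin <- rep(0, 3)
  structure(list(masks = masks, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "structure_set")
}

#' @export
print.structure_set <- function(x, ...) {
  cat(sprintf("<structure_set> %d structures on a %s grid:\n",
              length(x$masks), paste(dim(x$masks[[1]]), collapse = "x")))
  for (nm in names(x$masks))
    cat(sprintf("  %-14s %d voxels (%.1f cm^3)\n", nm, sum(x$masks[[nm]]),
                sum(x$masks[[nm]]) * prod(x$spacing) / 1000))
  invisible(x)
}

#' Extract one structure as a standalone mask
#' @param structs a `structure_set`.
#' @param name structure name.
#' @return list with `mask` (logical array), `spacing`, `origin`, `name`
#'   (class `structure_mask`).
#' @export
get_mask <- function(structs, name) {
  if (!name %in% names(structs$masks))
    stop(sprintf("no structure named '%s'", name))
  structure(list(mask = structs$masks[[name]], spacing = structs$spacing,
                 origin = structs$origin, name = name),
            class = "structure_mask")
}

as_mask_array <- function(m) {
  if (inherits(m, "structure_mask")) m$mask
  else if (is.array(m)) m
  else stop("expected a structure mask or logical array")
}

#' Centroid of a mask in world coordinates
#' @param m a `structure_mask`, or logical array (then `spacing`/`origin`
#'   must be given).
#' @param spacing,origin grid geometry when `m` is a bare array.
#' @return numeric length-3 (z, y, x), mm.
#' @export
mask_centroid <- function(m, spacing = NULL, origin = NULL) {
  if (inherits(m, "structure_mask")) {
    spacing <- m$spacing; origin <- m$origin; m <- m$mask
  }
  idx <- which(m, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty mask has no centroid")
  origin + (colMeans(idx) - 1) * spacing
}
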