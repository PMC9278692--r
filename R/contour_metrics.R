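# Structure-overlap assessment: Hausdorff distances on voxel-centre surface
# point sets in world mm, Dice coefficient, absolute volume difference.

shift_mask <- function(m, axis, by) {
  d <- dim(m)
  out <- array(FALSE, d)
  idx_src <- lapply(d, seq_len); idx_dst <- idx_src
  n <- d[axis]
  if (abs(by) >= n) return(out)
  if (by > 0) { idx_dst[[axis]] <- (1 + by):n; idx_src[[axis]] <- 1:(n - by) }
  else { idx_dst[[axis]] <- 1:(n + by); idx_src[[axis]] <- (1 - by):n }
  out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
    m[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  out
}

# boundary voxels: mask minus its face-connected erosion
mask_surface <- function(m) {
  inner <- m
  for (axis in 1:3) for (by in c(-1L, 1L))
    inner <- inner & shift_mask(m, axis, by)
  m & !inner
}

surface_points <- function(m, spacing, origin) {
  idx <- which(mask_surface(m), arr.ind = TRUE)
  sweep(sweep(idx - 1, 2, spacing, `*`), 2, origin, `+`)
}

# for each row of A, the distance to its nearest row of B (chunked)
directed_min_dists <- function(A, B, chunk = 512L) {
  out <- numeric(nrow(A))
  b2 <- rowSums(B^2)
  for (i0 in seq(1, nrow(A), by = chunk)) {
    i1 <- min(i0 + chunk - 1L, nrow(A))
    Ac <- A[i0:i1, , drop = FALSE]
    d2 <- outer(rowSums(Ac^2), b2, `+`) - 2 * Ac %*% t(B)
    out[i0:i1] <- sqrt(pmax(apply(d2, 1, min), 0))
  }
  out
}

coerce_mask <- function(x, name = "mask") {
  if (inherits(x, "structure_mask")) return(x)
  stop(sprintf("`%s` must be a structure_mask (see get_mask())", name))
}

#' Hausdorff distance between two structures, in mm
#'
#' Surfaces are the face-connectivity boundary voxels converted to
#' voxel-centre world coordinates (anisotropic spacing respected).
#' `mode = "max"` is the classic symmetric Hausdorff distance
#' (max of the two directed max-min distances); `mode = "mean"` is the
#' symmetric average of the directed mean surface distances.
#'
#' @param X,Y `structure_mask` objects on one grid, both non-empty.
#' @param mode "max" or "mean".
#' @return distance in mm; 0 iff the surfaces coincide.
#' @export
hausdorff <- function(X, Y, mode = c("max", "mean")) {
  mode <- match.arg(mode)
  X <- coerce_mask(X, "X"); Y <- coerce_mask(Y, "Y")
  stop_if_grid_mismatch(list(masks = list(X$mask), spacing = X$spacing, origin = X$origin),
                        list(masks = list(Y$mask), spacing = Y$spacing, origin = Y$origin),
                        "masks")
  if (sum(X$mask) == 0 || sum(Y$mask) == 0)
    stop("Hausdorff distance of an empty mask is undefined")
  A <- surface_points(X$mask, X$spacing, X$origin)
  B <- surface_points(Y$mask, Y$spacing, Y$origin)
  dab <- directed_min_dists(A, B)
  dba <- directed_min_dists(B, A)
  if (mode == "max") max(max(dab), max(dba))
  else (mean(dab) + mean(dba)) / 2
}

#' Dice similarity coefficient
#'
#' `2|X intersect Y| / (|X| + |Y|)`: 1 for identical masks, 0 for disjoint.
#' @param X,Y `structure_mask` objects on one grid.
#' @return fraction between 0 and 1.
#' @export
dice <- function(X, Y) {
  X <- coerce_mask(X, "X"); Y <- coerce_mask(Y, "Y")
  if (!identical(dim(X$mask), dim(Y$mask))) stop("masks must share a grid")
  nx <- sum(X$mask); ny <- sum(Y$mask)
  if (nx + ny == 0) stop("Dice of two empty masks is undefined")
  2 * sum(X$mask & Y$mask) / (nx + ny)
}

#' Absolute volume difference in cm^3
#' @param X,Y `structure_mask` objects with the same spacing.
#' @return cm^3.
#' @export
volume_diff <- function(X, Y) {
  X <- coerce_mask(X, "X"); Y <- coerce_mask(Y, "Y")
  if (max(abs(X$spacing - Y$spacing)) > 1e-9) stop("masks must share spacing")
  abs(sum(X$mask) - sum(Y$mask)) * prod(X$spacing) / 1000
}

#' Compare candidate contour sets against a reference
#'
#' Per organ and candidate: mean Hausdorff distance (mm), Dice coefficient,
#' and absolute volume difference (cc), plus a mean-over-organs row per
#' candidate. Organs missing from a candidate are flagged, not dropped.
#'
#' @param reference reference [structure_set] (the daily CBCT contours in
#'   the assessment this mirrors).
#' @param candidates named list of [structure_set].
#' @param organs organ names; default: all reference structures except
#'   `body`, `ptv` and `air_pockets`.
#' @return data.frame with columns `candidate`, `organ`,
#'   `mean_hausdorff_mm`, `dice`, `delta_v_cc`, `missing`.
#' @export
compare_contour_sets <- function(reference, candidates, organs = NULL) {
  if (is.null(names(candidates))) stop("candidates must be a named list")
  organs <- organs %||% setdiff(names(reference$masks),
                                c("body", "ptv", "air_pockets"))
  rows <- list()
  for (cn in names(candidates)) {
    cand <- candidates[[cn]]
    for (o in organs) {
      if (!o %in% names(cand$masks) || sum(cand$masks[[o]]) == 0) {
        rows[[length(rows) + 1]] <- data.frame(
          candidate = cn, organ = o, mean_hausdorff_mm = NA_real_,
          dice = NA_real_, delta_v_cc = NA_real_, missing = TRUE)
        next
      }
      rows[[length(rows) + 1]] <- data.frame(
        candidate = cn, organ = o,
        mean_hausdorff_mm = hausdorff(get_mask(reference, o),
                                      get_mask(cand, o), "mean"),
        dice = dice(get_mask(reference, o), get_mask(cand, o)),
        delta_v_cc = volume_diff(get_mask(reference, o), get_mask(cand, o)),
        missing = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  means <- do.call(rbind, lapply(split(tab, tab$candidate), function(d)
    data.frame(candidate = d$candidate[1], organ = "mean",
               mean_hausdorff_mm = mean(d$mean_hausdorff_mm, na.rm = TRUE),
               dice = mean(d$dice, na.rm = TRUE),
               delta_v_cc = mean(d$delta_v_cc, na.rm = TRUE),
               missing = any(d$missing))))
  out <- rbind(tab, means)
  rownames(out) <- NULL
  out
}
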