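# Image-quality and HU-accuracy assessment. All voxelwise metrics accept an
# optional evaluation mask; pipeline reports use the body mask by default so
# that the air background does not dominate.

metric_region <- function(r, t, mask = NULL) {
  stop_if_grid_mismatch(r, t, "reference and test volumes")
  rv <- r$data; tv <- t$data
  if (!is.null(mask)) {
    m <- as_mask_array(mask)
    if (!identical(dim(m), dim(rv))) stop("mask must be on the image grid")
    rv <- rv[m]; tv <- tv[m]
  }
  list(r = as.numeric(rv), t = as.numeric(tv))
}

#' Signal-to-noise ratio of a test image against a reference
#'
#' `10 log10( sum(r^2) / sum((r - t)^2) )` over the evaluation region.
#' Identical images return `Inf` (a sentinel, not an error).
#'
#' @param r reference [image_volume] (planning CT).
#' @param t test volume on the same grid.
#' @param mask optional evaluation mask.
#' @return decibels.
#' @export
snr <- function(r, t, mask = NULL) {
  z <- metric_region(r, t, mask)
  err <- sum((z$r - z$t)^2)
  if (err == 0) return(Inf)
  10 * log10(sum(z$r^2) / err)
}

#' Root-mean-square error in HU
#' @inheritParams snr
#' @return HU.
#' @export
rmse <- function(r, t, mask = NULL) {
  z <- metric_region(r, t, mask)
  sqrt(mean((z$r - z$t)^2))
}

#' Mean absolute error in HU
#' @inheritParams snr
#' @return HU; always <= [rmse()] on the same pair.
#' @export
mae <- function(r, t, mask = NULL) {
  z <- metric_region(r, t, mask)
  mean(abs(z$r - z$t))
}

#' Per-slice checkerboard composite of two volumes
#'
#' Each axial slice alternates n-by-n blocks from `a` and `b`, the top-left
#' block coming from `a`; used for visual edge-matching assessment.
#'
#' @param a,b volumes on one grid.
#' @param n squares per side (>= 2); block width is the integer division of
#'   the slice size, the remainder going to the last block.
#' @return an [image_volume].
#' @export
checkerboard <- function(a, b, n = 8) {
  stop_if_grid_mismatch(a, b)
  d <- dim(a$data)
  if (n < 2) stop("need at least 2 squares per side")
  if (n > min(d[2], d[3])) stop("more squares than slice pixels")
  block <- function(len) {
    bw <- len %/% n
    bi <- pmin((seq_len(len) - 1L) %/% bw, n - 1L)  # remainder -> last block
    bi
  }
  by <- block(d[2]); bx <- block(d[3])
  par <- outer(by, bx, `+`) %% 2L == 0L
  out <- a$data
  for (z in seq_len(d[1])) {
    sl <- a$data[z, , ]
    slb <- b$data[z, , ]
    sl[!par] <- slb[!par]
    out[z, , ] <- sl
  }
  image_volume(out, a$spacing, a$origin)
}

#' HU histogram of a volume
#'
#' Counts per bin over the whole volume (or a mask). Values outside `range`
#' are clipped into the end bins so counts always sum to the voxel count.
#'
#' @param vol an [image_volume].
#' @param bins number of bins.
#' @param range numeric length-2; default spans the data.
#' @param mask optional mask restricting the region.
#' @return data.frame with `bin_left`, `bin_right`, `count`.
#' @export
hu_histogram <- function(vol, bins = 100, range = NULL, mask = NULL) {
  v <- vol$data
  if (!is.null(mask)) v <- v[as_mask_array(mask)]
  v <- as.numeric(v)
  if (is.null(range)) range <- c(min(v), max(v) + 1e-9)
  if (diff(range) <= 0) stop("histogram range must have positive width")
  edges <- seq(range[1], range[2], length.out = bins + 1)
  v <- pmin(pmax(v, range[1]), range[2])
  idx <- pmin(findInterval(v, edges, rightmost.closed = TRUE), bins)
  counts <- tabulate(idx, nbins = bins)
  data.frame(bin_left = edges[-(bins + 1)], bin_right = edges[-1],
             count = counts)
}

#' Organ-wise HU statistics across subjects
#'
#' Per subject and organ: mean and SD of HU over the mask. The group summary
#' reports the mean of per-subject means and the segment variability as the
#' sum over subjects of the per-subject variances.
#'
#' @param vols an [image_volume] or list of them (one per subject).
#' @param structs matching [structure_set] or list.
#' @param organs organ names; defaults to all structures except `body` and
#'   `air_pockets`.
#' @return list with `per_subject` and `summary` data frames
#'   (class `organ_stats`).
#' @export
organ_hu_stats <- function(vols, structs, organs = NULL) {
  if (is_image_volume(vols)) { vols <- list(vols); structs <- list(structs) }
  if (length(vols) != length(structs)) stop("one structure set per subject")
  organs <- organs %||% setdiff(names(structs[[1]]$masks), c("body", "air_pockets"))
  rows <- list()
  for (s in seq_along(vols)) {
    for (o in organs) {
      m <- structs[[s]]$masks[[o]]
      if (is.null(m) || sum(m) == 0)
        stop(sprintf("empty or missing mask '%s' for subject %d", o, s))
      v <- vols[[s]]$data[m]
      rows[[length(rows) + 1]] <- data.frame(subject = s, organ = o,
                                             mean = mean(v), sd = sd(v),
                                             n_voxels = length(v))
    }
  }
  per <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(per, per$organ), function(d)
    data.frame(organ = d$organ[1], mean = mean(d$mean),
               sd = mean(d$sd), variability = sum(d$sd^2),
               n_subjects = nrow(d))))
  rownames(summ) <- NULL
  structure(list(per_subject = per, summary = summ), class = "organ_stats")
}
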