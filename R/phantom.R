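# Digital abdominal phantom: paired planning-CT / daily-CBCT generation with
# ground-truth masks. The phantom is built from ellipsoid / cylinder
# primitives painted with Gaussian HU textures; the CBCT degradation model
# adds cupping, per-tissue HU drift, in-plane blur, noise and streaks.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Define one phantom organ primitive
#'
#' @param name structure name; repeated names are merged into one mask
#'   (e.g. two lung lobes under "lungs").
#' @param shape "ellipsoid", "sphere" or "cylinder" (axis along z).
#' @param center world-mm centre (z, y, x); the phantom grid is centred on
#'   the world origin.
#' @param size semi-axes in mm: ellipsoid (az, ay, ax); sphere radius
#'   (scalar); cylinder (half-length z — may be `Inf` —, ry, rx).
#' @param mean,sd HU mean and standard deviation painted inside the organ.
#' @return list describing the organ.
#' @export
phantom_organ <- function(name, shape = c("ellipsoid", "sphere", "cylinder"),
                          center, size, mean, sd) {
  shape <- match.arg(shape)
  if (sd < 0) stop("organ HU sd must be >= 0")
  if (shape == "sphere" && length(size) != 1L) stop("sphere size is a single radius")
  if (shape != "sphere" && length(size) != 3L) stop("size must be (z, y, x) semi-axes")
  list(name = name, shape = shape, center = as.numeric(center),
       size = as.numeric(size), mean = mean, sd = sd)
}

#' Phantom specification
#'
#' @param grid_shape voxels per axis (z, y, x); each >= 16.
#' @param spacing mm per voxel (z, y, x).
#' @param body_semiaxes (y, x) semi-axes in mm of the elliptical body
#'   cross-section (the body is an elliptical cylinder along z).
#' @param organs list of [phantom_organ()] entries, painted in order
#'   (later entries win where organs overlap).
#' @param background_mean,background_sd soft-tissue background HU.
#' @param seed integer; every voxel of texture is a pure function of the
#'   spec plus this seed.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape, spacing, body_semiaxes, organs,
                         background_mean = 40, background_sd = 12, seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 16L))
    stop("grid_shape must be 3 integers, each >= 16")
  spacing <- as.numeric(spacing)
  if (any(spacing <= 0)) stop("spacing must be positive")
  if (length(body_semiaxes) != 2L || any(body_semiaxes <= 0))
    stop("body_semiaxes must be positive (y, x) semi-axes in mm")
  for (o in organs) if (o$sd < 0) stop("organ HU sd must be >= 0")
  structure(list(grid_shape = grid_shape, spacing = spacing,
                 body_semiaxes = as.numeric(body_semiaxes), organs = organs,
                 background_mean = background_mean,
                 background_sd = background_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Default abdominal phantom
#'
#' Organ HU means and standard deviations follow the planning-CT statistics
#' reported for upper-abdominal SBRT patients: aorta 40(4), spinal canal
#' 22(6), heart 36(2), bones 349(64), kidney 21(7), lungs -719(11),
#' liver 54(3) HU. A spherical PTV lesion sits inside the liver.
#'
#' @param seed integer texture seed.
#' @param grid_shape,spacing grid geometry; defaults give a
#'   128 x 224 x 224 mm field of view at desk scale.
#' @return a [phantom_spec].
#' @export
default_phantom_spec <- function(seed = 1L, grid_shape = c(32, 64, 64),
                                 spacing = c(4, 3.5, 3.5)) {
  organs <- list(
    phantom_organ("lungs", "ellipsoid", c(38, -15, -58), c(22, 40, 34), -719, 11),
    phantom_organ("lungs", "ellipsoid", c(38, -15, 58), c(22, 40, 34), -719, 11),
    phantom_organ("liver", "ellipsoid", c(-5, 5, 45), c(45, 55, 50), 54, 3),
    phantom_organ("heart", "ellipsoid", c(45, -30, -10), c(16, 28, 30), 36, 2),
    phantom_organ("kidney", "ellipsoid", c(-35, 45, -45), c(25, 18, 14), 21, 7),
    phantom_organ("kidney", "ellipsoid", c(-35, 45, 45), c(25, 18, 14), 21, 7),
    phantom_organ("bones", "cylinder", c(0, 60, 0), c(Inf, 22, 24), 349, 64),
    phantom_organ("spinal_canal", "cylinder", c(0, 60, 0), c(Inf, 9, 9), 22, 6),
    phantom_organ("aorta", "cylinder", c(0, 28, -10), c(Inf, 11, 11), 40, 4),
    phantom_organ("ptv", "sphere", c(-5, 0, 55), 24, 60, 5)
  )
  phantom_spec(grid_shape, spacing, body_semiaxes = c(95, 105),
               organs = organs, seed = seed)
}

# world-coordinate arrays of the voxel centres (grid centred on origin 0)
phantom_grid <- function(spec) {
  d <- spec$grid_shape
  origin <- -(d - 1) * spec$spacing / 2
  zc <- origin[1] + (seq_len(d[1]) - 1) * spec$spacing[1]
  yc <- origin[2] + (seq_len(d[2]) - 1) * spec$spacing[2]
  xc <- origin[3] + (seq_len(d[3]) - 1) * spec$spacing[3]
  list(origin = origin,
       Z = array(rep(zc, times = d[2] * d[3]), dim = d),
       Y = array(rep(rep(yc, each = d[1]), times = d[3]), dim = d),
       X = array(rep(xc, each = d[1] * d[2]), dim = d))
}

organ_inside <- function(o, g) {
  cz <- o$center[1]; cy <- o$center[2]; cx <- o$center[3]
  switch(o$shape,
    sphere = ((g$Z - cz)^2 + (g$Y - cy)^2 + (g$X - cx)^2) <= o$size[1]^2,
    ellipsoid = ((g$Z - cz) / o$size[1])^2 + ((g$Y - cy) / o$size[2])^2 +
      ((g$X - cx) / o$size[3])^2 <= 1,
    cylinder = (((g$Y - cy) / o$size[2])^2 + ((g$X - cx) / o$size[3])^2 <= 1) &
      (abs(g$Z - cz) <= o$size[1]))
}

#' Generate a planning-CT phantom and its ground-truth structures
#'
#' Paints each organ as `mean + N(0, sd)` HU over a soft-tissue background
#' inside an elliptical-cylinder body; air (-1000 HU) outside. Organs are
#' painted in listed order, later organs winning in overlaps; returned masks
#' are exclusive (a voxel belongs to the organ that owns its HU). Output is
#' bit-reproducible given the spec seed.
#'
#' @param spec a [phantom_spec].
#' @return list with `volume` ([image_volume]) and `structures`
#'   ([structure_set]; includes every organ, `ptv` if specified, and `body`).
#'   The spec is attached to the structure set as attribute `phantom_spec`
#'   so that anatomy can be re-generated under perturbation.
#' @export
make_phantom_ct <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- phantom_grid(spec)
  d <- spec$grid_shape
  extent_lo <- g$origin - spec$spacing / 2
  extent_hi <- -extent_lo
  body <- (g$Y / spec$body_semiaxes[1])^2 + (g$X / spec$body_semiaxes[2])^2 <= 1

  label <- array(0L, dim = d)  # 0 air, -1 background, k = organ entry k
  organ_masks <- vector("list", length(spec$organs))
  for (k in seq_along(spec$organs)) {
    o <- spec$organs[[k]]
    lo <- o$center - if (o$shape == "sphere") o$size else o$size
    hi <- o$center + if (o$shape == "sphere") o$size else o$size
    finite <- is.finite(lo) & is.finite(hi)
    if (any(lo[finite] < extent_lo[finite]) || any(hi[finite] > extent_hi[finite]))
      stop(sprintf("organ '%s' extends outside the grid", o$name))
    m <- organ_inside(o, g)
    if (any(m & !body))
      stop(sprintf("organ '%s' extends outside the body", o$name))
    organ_masks[[k]] <- m
    label[m] <- k
  }
  label[body & label == 0L] <- -1L

  vol <- array(-1000, dim = d)
  with_seed(spec$seed, {
    nbg <- sum(label == -1L)
    vol[label == -1L] <- spec$background_mean + rnorm(nbg, 0, spec$background_sd)
    for (k in seq_along(spec$organs)) {
      o <- spec$organs[[k]]
      own <- label == k
      vol[own] <- o$mean + rnorm(sum(own), 0, o$sd)
    }
  })

  masks <- list()
  for (nm in unique(vapply(spec$organs, `[[`, "", "name"))) {
    ks <- which(vapply(spec$organs, `[[`, "", "name") == nm)
    masks[[nm]] <- array(label %in% ks, dim = d)
  }
  masks$body <- body
  structs <- structure_set(masks, spec$spacing, g$origin)
  attr(structs, "phantom_spec") <- spec
  list(volume = image_volume(vol, spec$spacing, g$origin), structures = structs)
}

#' CBCT degradation specification
#'
#' The defaults are calibrated so that the net organ-mean drift (per-tissue
#' bias plus the cupping and blur contributions at each organ's depth)
#' reproduces the CBCT organ statistics observed clinically: heart 36 to
#' ~74 HU, lungs -719 to ~-600 HU, liver 54 to ~38 HU, and so on. The
#' per-tissue bias values therefore over/under-shoot their targets by the
#' cupping depression the organ sits in.
#'
#' @param cupping HU depression at the body centre (0 at the surface).
#' @param noise_sigma Gaussian noise sd in HU, inside the body.
#' @param streak_count,streak_amplitude number and peak HU of randomly
#'   oriented thin linear streaks (Gaussian-profile ridges, alternating sign).
#' @param tissue_bias named HU shifts applied per organ class.
#' @param blur_fwhm in-plane Gaussian blur FWHM in mm (resolution loss).
#' @param seed integer.
#' @return object of class `degradation_spec`.
#' @export
degradation_spec <- function(cupping = 40, noise_sigma = 25,
                             streak_count = 12, streak_amplitude = 60,
                             tissue_bias = c(aorta = 60, spinal_canal = 19,
                                             heart = 74, bones = 55,
                                             kidney = 7, lungs = 144,
                                             liver = 11),
                             blur_fwhm = 2, seed = 1L) {
  if (noise_sigma < 0) stop("noise sigma must be >= 0")
  if (streak_count < 0) stop("streak count must be >= 0")
  if (blur_fwhm < 0) stop("blur FWHM must be >= 0")
  structure(list(cupping = cupping, noise_sigma = noise_sigma,
                 streak_count = as.integer(streak_count),
                 streak_amplitude = streak_amplitude,
                 tissue_bias = tissue_bias, blur_fwhm = blur_fwhm,
                 seed = as.integer(seed)),
            class = "degradation_spec")
}

#' Degrade a CT phantom into a CBCT-like volume
#'
#' Applies, in order: per-tissue HU bias, a radially increasing cupping bias
#' (0 at the body surface, -`cupping` at the centre), in-plane Gaussian blur,
#' Gaussian noise, and thin oriented streaks. All degradation is confined to
#' the body; air outside is untouched. Deterministic given `spec$seed`.
#'
#' @param ct an [image_volume].
#' @param body body mask: a `structure_mask`, logical array, or a
#'   [structure_set] containing "body".
#' @param spec a [degradation_spec].
#' @param structs optional [structure_set] supplying the organ masks that
#'   `spec$tissue_bias` refers to; required when any bias is non-zero.
#' @return an [image_volume] on the same grid.
#' @export
degrade_to_cbct <- function(ct, body, spec, structs = NULL) {
  stopifnot(is_image_volume(ct), inherits(spec, "degradation_spec"))
  if (spec$noise_sigma < 0) stop("noise sigma must be >= 0")
  if (inherits(body, "structure_set")) { structs <- structs %||% body; body <- get_mask(body, "body") }
  bm <- as_mask_array(body)
  if (!identical(dim(bm), dim(ct$data))) stop("ct and body must share a grid")
  d <- dim(ct$data)
  out <- ct$data

  bias <- spec$tissue_bias[spec$tissue_bias != 0]
  if (length(bias) > 0) {
    if (is.null(structs))
      stop("per-tissue bias requires `structs` with the named organ masks")
    for (nm in names(bias)) {
      if (!nm %in% names(structs$masks)) next
      out[structs$masks[[nm]]] <- out[structs$masks[[nm]]] + bias[[nm]]
    }
  }

  if (spec$cupping != 0) {
    # normalized elliptic radius from the body cross-section (1 at surface)
    sl <- which(bm[ceiling(d[1] / 2), , ], arr.ind = TRUE)
    cy <- mean(range(sl[, 1])); cx <- mean(range(sl[, 2]))
    ry <- diff(range(sl[, 1])) / 2 + 0.5; rx <- diff(range(sl[, 2])) / 2 + 0.5
    yv <- (seq_len(d[2]) - cy) / ry
    xv <- (seq_len(d[3]) - cx) / rx
    rho2 <- outer(yv^2, xv^2, `+`)
    rho2[rho2 > 1] <- 1
    cup <- -spec$cupping * (1 - rho2)
    cup3 <- aperm(array(cup, dim = c(d[2], d[3], d[1])), c(3, 1, 2))
    out[bm] <- out[bm] + cup3[bm]
  }

  if (spec$blur_fwhm > 0) {
    sig_mm <- spec$blur_fwhm / (2 * sqrt(2 * log(2)))
    blurred <- .blur_inplane(out, sig_mm / ct$spacing[2], sig_mm / ct$spacing[3])
    out[bm] <- blurred[bm]
  }

  with_seed(spec$seed, {
    if (spec$noise_sigma > 0)
      out[bm] <- out[bm] + rnorm(sum(bm), 0, spec$noise_sigma)
    if (spec$streak_count > 0 && spec$streak_amplitude != 0) {
      yw <- ct$origin[2] + (seq_len(d[2]) - 1) * ct$spacing[2]
      xw <- ct$origin[3] + (seq_len(d[3]) - 1) * ct$spacing[3]
      Yp <- matrix(yw, d[2], d[3])
      Xp <- matrix(xw, d[2], d[3], byrow = TRUE)
      ridge <- matrix(0, d[2], d[3])
      w <- 2  # ridge Gaussian sigma, mm
      for (k in seq_len(spec$streak_count)) {
        th <- runif(1, 0, pi)
        y0 <- runif(1, min(yw) * 0.6, max(yw) * 0.6)
        x0 <- runif(1, min(xw) * 0.6, max(xw) * 0.6)
        a <- spec$streak_amplitude * runif(1, 0.4, 1) * sample(c(-1, 1), 1)
        dist <- abs(-sin(th) * (Yp - y0) + cos(th) * (Xp - x0))
        ridge <- ridge + a * exp(-dist^2 / (2 * w^2))
      }
      ridge3 <- aperm(array(ridge, dim = c(d[2], d[3], d[1])), c(3, 1, 2))
      out[bm] <- out[bm] + ridge3[bm]
    }
  })

  image_volume(out, ct$spacing, ct$origin)
}

#' Inter-fraction anatomy perturbation
#'
#' @param organ_shifts named list of (z, y, x) mm rigid shifts applied to the
#'   organ centres before re-generation.
#' @param air_pockets list of `list(center = c(z, y, x) mm, radius = mm)`
#'   spheres carved to -1000 HU (new structures the daily anatomy gained).
#' @param deform_amplitude,deform_corr maximum displacement (mm) and
#'   correlation length (mm) of a smooth random residual deformation field.
#' @param max_shift upper bound on any organ shift component (mm).
#' @param seed integer.
#' @return object of class `anatomy_perturbation`.
#' @export
anatomy_perturbation <- function(organ_shifts = list(), air_pockets = list(),
                                 deform_amplitude = 0, deform_corr = 40,
                                 max_shift = 10, seed = 1L) {
  for (s in organ_shifts)
    if (length(s) != 3L || any(abs(s) > max_shift))
      stop(sprintf("organ shifts must be (z,y,x) mm with |shift| <= %g mm", max_shift))
  for (p in air_pockets)
    if (is.null(p$radius) || p$radius <= 0) stop("air pocket radii must be > 0")
  if (deform_amplitude < 0 || deform_corr <= 0)
    stop("deformation amplitude must be >= 0 and correlation length > 0")
  structure(list(organ_shifts = organ_shifts, air_pockets = air_pockets,
                 deform_amplitude = deform_amplitude,
                 deform_corr = deform_corr, max_shift = max_shift,
                 seed = as.integer(seed)),
            class = "anatomy_perturbation")
}

# smooth random vector field: white noise on a coarse grid (node spacing =
# correlation length) upsampled trilinearly, then scaled to a max norm
smooth_field <- function(dims, spacing, origin, amplitude, corr, seed) {
  extent <- (dims - 1) * spacing
  cdim <- pmax(2L, as.integer(ceiling(extent / corr)) + 2L)
  corigin <- origin - corr
  comp <- with_seed(seed, lapply(1:3, function(a)
    array(rnorm(prod(cdim)), dim = cdim)))
  up <- lapply(comp, function(f)
    .resample_tri(f, corigin, rep(corr, 3), as.integer(dims), origin, spacing)$values)
  nrm <- sqrt(up[[1]]^2 + up[[2]]^2 + up[[3]]^2)
  scale <- amplitude / max(nrm)
  lapply(up, function(f) f * scale)
}

warp_pair <- function(vol, structs, field) {
  wdata <- .warp_vol(vol$data, field[[1]], field[[2]], field[[3]], vol$spacing, 1L)
  wmasks <- lapply(structs$masks, function(m) {
    wm <- .warp_vol(array(as.numeric(m), dim = dim(m)),
                    field[[1]], field[[2]], field[[3]], vol$spacing, 0L)
    array(wm > 0.5, dim = dim(m))
  })
  ws <- structure_set(wmasks, structs$spacing, structs$origin)
  attr(ws, "phantom_spec") <- attr(structs, "phantom_spec")
  list(volume = image_volume(wdata, vol$spacing, vol$origin), structures = ws)
}

#' Apply an inter-fraction anatomy change to a phantom
#'
#' Re-generates the phantom with shifted organ centres (using the spec stored
#' in the structure set), applies a smooth random residual deformation, and
#' carves the requested air pockets. Masks are transformed consistently and
#' an `air_pockets` structure is added when pockets are present.
#'
#' @param ct phantom [image_volume] from [make_phantom_ct()].
#' @param structs matching [structure_set] (carries the `phantom_spec` attribute).
#' @param p an [anatomy_perturbation].
#' @return list with `volume` and `structures`.
#' @export
perturb_anatomy <- function(ct, structs, p) {
  stopifnot(inherits(p, "anatomy_perturbation"))
  if (length(p$organ_shifts) == 0 && length(p$air_pockets) == 0 &&
      p$deform_amplitude == 0)
    return(list(volume = ct, structures = structs))
  spec <- attr(structs, "phantom_spec")
  if (is.null(spec))
    stop("structure set does not carry a phantom_spec; cannot re-generate anatomy")
  for (nm in names(p$organ_shifts)) {
    s <- p$organ_shifts[[nm]]
    if (any(abs(s) > p$max_shift))
      stop(sprintf("shift for '%s' exceeds the %g mm bound", nm, p$max_shift))
    for (k in seq_along(spec$organs))
      if (spec$organs[[k]]$name == nm)
        spec$organs[[k]]$center <- spec$organs[[k]]$center + s
  }
  ph <- make_phantom_ct(spec)
  vol <- ph$volume; st <- ph$structures

  if (p$deform_amplitude > 0) {
    f <- smooth_field(dim(vol$data), vol$spacing, vol$origin,
                      p$deform_amplitude, p$deform_corr,
                      derive_seed(p$seed, "deform"))
    wp <- warp_pair(vol, st, f)
    vol <- wp$volume; st <- wp$structures
  }

  if (length(p$air_pockets) > 0) {
    g <- phantom_grid(spec)
    body <- st$masks$body
    pocket_all <- array(FALSE, dim = dim(vol$data))
    for (pk in p$air_pockets) {
      m <- ((g$Z - pk$center[1])^2 + (g$Y - pk$center[2])^2 +
              (g$X - pk$center[3])^2) <= pk$radius^2
      if (any(m & !body)) stop("air pocket outside the body rejected")
      pocket_all <- pocket_all | m
    }
    vd <- vol$data
    vd[pocket_all] <- -1000
    vol <- image_volume(vd, vol$spacing, vol$origin)
    masks <- lapply(st$masks, function(m) m & !pocket_all)
    masks$body <- st$masks$body      # pockets stay part of the body interior
    masks$air_pockets <- pocket_all
    st2 <- structure_set(masks, st$spacing, st$origin)
    attr(st2, "phantom_spec") <- spec
    st <- st2
  } else {
    attr(st, "phantom_spec") <- spec
  }
  list(volume = vol, structures = st)
}

#' Deformed-CT surrogate with controlled residual registration error
#'
#' Stands in for a clinically deformably-registered planning CT: the daily
#' phantom carried through a smooth misalignment field whose maximum
#' displacement equals `err` mm exactly, contours included. `err = 0`
#' returns the daily phantom unchanged.
#'
#' @param ct daily phantom [image_volume].
#' @param structs daily [structure_set].
#' @param err maximum residual displacement in mm (>= 0).
#' @param corr correlation length of the misalignment field, mm.
#' @param seed integer.
#' @return list with `volume`, `structures`, and `field` (the applied
#'   displacement components, mm).
#' @export
make_ctdef_surrogate <- function(ct, structs, err, corr = 60, seed = 1L) {
  if (err < 0) stop("err must be >= 0")
  if (err == 0)
    return(list(volume = ct, structures = structs, field = NULL))
  f <- smooth_field(dim(ct$data), ct$spacing, ct$origin, err, corr,
                    derive_seed(seed, "ctdef"))
  wp <- warp_pair(ct, structs, f)
  c(wp, list(field = f))
}

# small reproducible inter-subject geometry jitter (HU targets untouched)
vary_spec <- function(spec, seed) {
  with_seed(seed, {
    for (k in seq_along(spec$organs)) {
      o <- spec$organs[[k]]
      jit <- rnorm(3, 0, 2)
      o$center <- o$center + c(0, jit[2], jit[3]) * 0.8
      scl <- runif(1, 0.95, 1.05)
      o$size <- ifelse(is.finite(o$size), o$size * scl, o$size)
      spec$organs[[k]] <- o
    }
    spec
  })
}

default_daily_perturbation <- function(seed, spec) {
  organs <- unique(vapply(spec$organs, `[[`, "", "name"))
  with_seed(seed, {
    shifts <- list()
    for (nm in intersect(c("liver", "kidney", "ptv"), organs))
      shifts[[nm]] <- pmin(8, pmax(-8, rnorm(3, 0, c(1.5, 2.5, 2.5))))
    # an anterior bowel gas pocket, scaled to the body cross-section
    by <- spec$body_semiaxes[1]; bx <- spec$body_semiaxes[2]
    zext <- (spec$grid_shape[1] - 1) * spec$spacing[1] / 2
    pocket <- list(center = c(runif(1, -0.3, 0.3) * zext,
                              -0.5 * by + runif(1, -3, 3),
                              -0.5 * bx + runif(1, -3, 3)),
                   radius = min(runif(1, 7, 10), 0.18 * min(by, bx)))
    anatomy_perturbation(shifts, list(pocket), deform_amplitude = 3,
                         deform_corr = 50, seed = derive_seed(seed, "warp"))
  })
}

#' Generate a multi-subject phantom dataset on disk
#'
#' For every subject: a planning CT, a daily anatomy (perturbed planning CT,
#' the ground truth for evaluation), its CBCT degradation, and a 7 mm-class
#' deformed-CT surrogate, all with structure masks, written as NIfTI with
#' JSON sidecars. Subjects are split train/test in the same 11:6 proportion
#' used for the clinical cohort.
#'
#' @param n_subjects cohort size, at least 2.
#' @param out_dir output directory (created if missing).
#' @param spec template [phantom_spec]; per-subject geometry is jittered and
#'   the texture seed re-derived from `master_seed`.
#' @param degradation a [degradation_spec] template.
#' @param ctdef_err residual registration error of the surrogate, mm.
#' @param master_seed integer; all per-subject and per-stage seeds derive
#'   from it by fixed hashing.
#' @param train_frac train fraction (default 11/17).
#' @return the manifest (list), invisibly; also written to
#'   `out_dir/manifest.json`.
#' @export
generate_dataset <- function(n_subjects, out_dir,
                             spec = default_phantom_spec(),
                             degradation = degradation_spec(),
                             ctdef_err = 7, master_seed = 1L,
                             train_frac = 11 / 17) {
  if (n_subjects < 2) stop("need at least 2 subjects to form a train/test split")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop(sprintf("cannot create output directory %s", out_dir))
  n_train <- max(1L, min(n_subjects - 1L, as.integer(round(n_subjects * train_frac))))
  cfg_hash <- config_hash(list(spec = spec, degradation = degradation,
                               ctdef_err = ctdef_err, master_seed = master_seed))
  subjects <- list()
  for (s in seq_len(n_subjects)) {
    id <- sprintf("S%02d", s)
    sdir <- file.path(out_dir, id)
    seed_s <- derive_seed(master_seed, "subject", s)
    spec_s <- vary_spec(spec, derive_seed(seed_s, "geom"))
    spec_s$seed <- derive_seed(seed_s, "texture")
    planning <- make_phantom_ct(spec_s)
    daily <- perturb_anatomy(planning$volume, planning$structures,
                             default_daily_perturbation(derive_seed(seed_s, "daily"),
                                                        spec_s))
    deg <- degradation
    deg$seed <- derive_seed(seed_s, "cbct")
    cbct <- degrade_to_cbct(daily$volume, daily$structures, deg)
    ctdef <- make_ctdef_surrogate(daily$volume, daily$structures, ctdef_err,
                                  seed = derive_seed(seed_s, "ctdef"))
    meta <- list(subject = id, seed = seed_s, config_hash = cfg_hash)
    write_volume(planning$volume, file.path(sdir, "ct.nii.gz"), sidecar = meta)
    write_volume(daily$volume, file.path(sdir, "ct_daily.nii.gz"), sidecar = meta)
    write_volume(cbct, file.path(sdir, "cbct.nii.gz"), sidecar = meta)
    write_volume(ctdef$volume, file.path(sdir, "ctdef.nii.gz"), sidecar = meta)
    write_structures(planning$structures, file.path(sdir, "masks_planning"), sidecar = meta)
    write_structures(daily$structures, file.path(sdir, "masks_daily"), sidecar = meta)
    write_structures(ctdef$structures, file.path(sdir, "masks_ctdef"), sidecar = meta)
    subjects[[s]] <- list(
      id = id, role = if (s <= n_train) "train" else "test", seed = seed_s,
      ct = file.path(sdir, "ct.nii.gz"),
      ct_daily = file.path(sdir, "ct_daily.nii.gz"),
      cbct = file.path(sdir, "cbct.nii.gz"),
      ctdef = file.path(sdir, "ctdef.nii.gz"),
      masks_planning = file.path(sdir, "masks_planning"),
      masks_daily = file.path(sdir, "masks_daily"),
      masks_ctdef = file.path(sdir, "masks_ctdef"))
  }
  manifest <- list(package = "adaptsct", master_seed = master_seed,
                   config_hash = cfg_hash, n_train = n_train,
                   n_test = n_subjects - n_train, ctdef_err = ctdef_err,
                   subjects = subjects)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' @rdname generate_dataset
#' @param path path to a `manifest.json`.
#' @export
load_manifest <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "manifest.json")
  jsonlite::read_json(path, simplifyVector = FALSE)
}
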