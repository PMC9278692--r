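test_that("phantom organs recover their specified HU statistics", {
  ph <- make_phantom_ct(default_phantom_spec(seed = 11))
  spec <- attr(ph$structures, "phantom_spec")
  for (o in spec$organs) {
    m <- ph$structures$masks[[o$name]]
    vals <- ph$volume$data[m]
    se <- o$sd / sqrt(length(vals))
    expect_lt(abs(mean(vals) - o$mean), max(3 * se, 1e-9),
              label = sprintf("organ %s mean", o$name))
  }
  # spec-level checks: liver 54 +- 1 and lungs -719 +- 5
  expect_lt(abs(mean(ph$volume$data[ph$structures$masks$liver]) - 54), 1)
  expect_lt(abs(mean(ph$volume$data[ph$structures$masks$lungs]) + 719), 5)
  # air outside the body
  expect_true(all(ph$volume$data[!ph$structures$masks$body] == -1000))
})

test_that("phantom generation is bit-reproducible and masks are consistent", {
  a <- make_phantom_ct(default_phantom_spec(seed = 4))
  b <- make_phantom_ct(default_phantom_spec(seed = 4))
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$structures$masks, b$structures$masks)
  c <- make_phantom_ct(default_phantom_spec(seed = 5))
  expect_false(identical(a$volume$data, c$volume$data))

  # every organ strictly inside the body; organ masks mutually exclusive
  body <- a$structures$masks$body
  organs <- setdiff(names(a$structures$masks), "body")
  lab <- array(0L, dim(body))
  for (nm in organs) {
    expect_true(all(body[a$structures$masks[[nm]]]), label = nm)
    lab <- lab + a$structures$masks[[nm]]
  }
  expect_true(all(lab <= 1L))
})

test_that("voxelized organ volumes match the analytic primitives", {
  ph <- make_phantom_ct(default_phantom_spec(seed = 2))
  spec <- attr(ph$structures, "phantom_spec")
  vox <- prod(spec$spacing)
  analytic <- function(o, zlen) {
    switch(o$shape,
           sphere = 4 / 3 * pi * o$size[1]^3,
           ellipsoid = 4 / 3 * pi * prod(o$size),
           cylinder = pi * o$size[2] * o$size[3] *
             min(2 * o$size[1], zlen))
  }
  zlen <- spec$grid_shape[1] * spec$spacing[1]
  # organs painted last in their overlap groups keep their full volume
  for (nm in c("heart", "kidney", "spinal_canal", "aorta", "ptv")) {
    os <- Filter(function(o) o$name == nm, spec$organs)
    va <- sum(vapply(os, analytic, 0, zlen = zlen))
    vm <- sum(ph$structures$masks[[nm]]) * vox
    expect_lt(abs(vm - va) / va, 0.05, label = sprintf("volume of %s", nm))
  }
})

test_that("invalid phantom specs are rejected", {
  expect_error(phantom_spec(c(8, 24, 24), c(4, 4, 4), c(40, 44), list()),
               ">= 16")
  expect_error(phantom_organ("x", "sphere", c(0, 0, 0), 5, 0, -1), "sd")
  sp <- tiny_spec()
  sp$organs[[1]]$center <- c(0, 5, 200)
  expect_error(make_phantom_ct(sp), "outside the grid")
  sp2 <- tiny_spec()
  sp2$organs[[1]]$center <- c(0, 30, 30)  # inside grid, pokes out of body
  expect_error(make_phantom_ct(sp2), "outside the body")
})

test_that("a zero degradation spec is the identity", {
  ph <- make_phantom_ct(tiny_spec(6))
  z <- degradation_spec(cupping = 0, noise_sigma = 0, streak_count = 0,
                        tissue_bias = c(), blur_fwhm = 0)
  cb <- degrade_to_cbct(ph$volume, ph$structures, z)
  expect_identical(cb$data, ph$volume$data)
  expect_error(degradation_spec(noise_sigma = -1), "sigma")
})

test_that("per-tissue bias reproduces the intended organ-mean drift", {
  ph <- make_phantom_ct(default_phantom_spec(seed = 9))
  sp <- degradation_spec(cupping = 0, noise_sigma = 0, streak_count = 0,
                         tissue_bias = c(heart = 38), blur_fwhm = 0, seed = 2)
  cb <- degrade_to_cbct(ph$volume, ph$structures, sp, ph$structures)
  hm <- mean(cb$data[ph$structures$masks$heart])
  expect_lt(abs(hm - 74), 2)  # heart 36 + 38
  # other organs untouched
  expect_identical(cb$data[ph$structures$masks$liver],
                   ph$volume$data[ph$structures$masks$liver])
})

test_that("noise-only degradation has RMSE ~ sigma and leaves air alone", {
  ph <- make_phantom_ct(tiny_spec(8))
  sp <- degradation_spec(cupping = 0, noise_sigma = 20, streak_count = 0,
                         tissue_bias = c(), blur_fwhm = 0, seed = 31)
  cb <- degrade_to_cbct(ph$volume, ph$structures, sp)
  body <- get_mask(ph$structures, "body")
  r <- rmse(ph$volume, cb, body)
  expect_lt(abs(r - 20) / 20, 0.1)
  expect_identical(cb$data[!body$mask], ph$volume$data[!body$mask])
  # determinism
  cb2 <- degrade_to_cbct(ph$volume, ph$structures, sp)
  expect_identical(cb$data, cb2$data)
})

test_that("degradation severity is monotone in the noise level", {
  ph <- make_phantom_ct(tiny_spec(12))
  sev <- function(sigma) {
    mean(vapply(1:5, function(s) {
      sp <- degradation_spec(cupping = 0, noise_sigma = sigma,
                             streak_count = 0, tissue_bias = c(),
                             blur_fwhm = 0, seed = s)
      mae(ph$volume, degrade_to_cbct(ph$volume, ph$structures, sp),
          get_mask(ph$structures, "body"))
    }, 0))
  }
  m <- vapply(c(5, 15, 30), sev, 0)
  expect_true(all(diff(m) > 0))
})

test_that("anatomy perturbation shifts organs and carves air pockets", {
  ph <- make_phantom_ct(tiny_spec(21))
  # zero perturbation is the identity
  p0 <- anatomy_perturbation()
  out0 <- perturb_anatomy(ph$volume, ph$structures, p0)
  expect_identical(out0$volume$data, ph$volume$data)

  # pure +5 mm y shift of the liver moves its centroid by 5 mm (+- half voxel)
  p <- anatomy_perturbation(organ_shifts = list(liver = c(0, 5, 0)))
  out <- perturb_anatomy(ph$volume, ph$structures, p)
  c0 <- mask_centroid(get_mask(ph$structures, "liver"))
  c1 <- mask_centroid(get_mask(out$structures, "liver"))
  expect_lt(abs((c1 - c0)[2] - 5), ph$volume$spacing[2] / 2)
  expect_lt(abs((c1 - c0)[3]), ph$volume$spacing[3] / 2)

  # air pocket volume matches both its own voxelization and the analytic value
  pk <- anatomy_perturbation(air_pockets = list(list(center = c(0, -20, -20),
                                                     radius = 8)))
  outp <- perturb_anatomy(ph$volume, ph$structures, pk)
  vpock <- sum(outp$structures$masks$air_pockets) * voxel_volume(ph$volume)
  ns <- asNamespace("adaptsct")
  g <- ns$phantom_grid(tiny_spec(21))
  nvox <- sum((g$Z - 0)^2 + (g$Y + 20)^2 + (g$X + 20)^2 <= 64)
  expect_equal(sum(outp$structures$masks$air_pockets), nvox)
  expect_lt(abs(vpock - 4 / 3 * pi * 8^3) / (4 / 3 * pi * 8^3), 0.25)
  expect_true(all(outp$volume$data[outp$structures$masks$air_pockets] == -1000))

  expect_error(perturb_anatomy(ph$volume, ph$structures,
                               anatomy_perturbation(air_pockets = list(
                                 list(center = c(0, 38, 40), radius = 8)))),
               "outside the body")
  expect_error(anatomy_perturbation(organ_shifts = list(liver = c(0, 15, 0))),
               "10")
})

test_that("deformed-CT surrogate applies a bounded smooth misalignment", {
  ph <- make_phantom_ct(tiny_spec(31))
  s0 <- make_ctdef_surrogate(ph$volume, ph$structures, 0)
  expect_identical(s0$volume$data, ph$volume$data)

  s7 <- make_ctdef_surrogate(ph$volume, ph$structures, 7, seed = 3)
  mx <- max(sqrt(s7$field[[1]]^2 + s7$field[[2]]^2 + s7$field[[3]]^2))
  expect_lt(abs(mx - 7), 0.1)
  d <- dice(get_mask(ph$structures, "liver"), get_mask(s7$structures, "liver"))
  expect_lt(d, 1)
  expect_gt(d, 0.5)
  expect_error(make_ctdef_surrogate(ph$volume, ph$structures, -1), ">= 0")
})

test_that("dataset generation writes a reproducible split manifest", {
  d1 <- file.path(tempdir(), "ds1")
  d2 <- file.path(tempdir(), "ds2")
  m1 <- generate_dataset(3, d1, spec = tiny_spec(), master_seed = 77)
  m2 <- generate_dataset(3, d2, spec = tiny_spec(), master_seed = 77)
  expect_equal(m1$config_hash, m2$config_hash)
  expect_equal(vapply(m1$subjects, `[[`, 1L, "seed"),
               vapply(m2$subjects, `[[`, 1L, "seed"))
  v1 <- read_volume(m1$subjects[[1]]$cbct)
  v2 <- read_volume(m2$subjects[[1]]$cbct)
  expect_identical(v1$data, v2$data)

  roles <- vapply(m1$subjects, `[[`, "", "role")
  expect_equal(sum(roles == "train"), 2L)
  expect_equal(sum(roles == "test"), 1L)

  # the 17-subject cohort splits 11 train / 6 test
  m17 <- generate_dataset(17, file.path(tempdir(), "ds17"),
                          spec = tiny_spec(), master_seed = 5)
  roles17 <- vapply(m17$subjects, `[[`, "", "role")
  expect_equal(sum(roles17 == "train"), 11L)
  expect_equal(sum(roles17 == "test"), 6L)

  man <- jsonlite::read_json(file.path(d1, "manifest.json"))
  expect_equal(man$master_seed, 77)
  expect_error(generate_dataset(1, tempdir()), "at least 2")
})
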