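test_that("cumulative DVHs are exact step functions", {
  d <- dose_from(array(50, c(4, 5, 5)), prescription = 50)
  m <- mask_from(as.matrix(expand.grid(2:3, 2:4, 2:4)), c(4, 5, 5))
  dvh <- compute_dvh(d, m, bin_width = 1)
  expect_equal(dvh$volume[dvh$dose <= 50], rep(1, sum(dvh$dose <= 50)))
  expect_equal(dvh$volume[dvh$dose > 50], rep(0, sum(dvh$dose > 50)))

  # two-voxel mask at 1 and 2 Gy
  d2 <- dose_from(array(0, c(1, 1, 4)))
  d2$data[1, 1, 1] <- 1; d2$data[1, 1, 2] <- 2
  m2 <- mask_from(rbind(c(1, 1, 1), c(1, 1, 2)), c(1, 1, 4))
  dvh2 <- compute_dvh(d2, m2, bin_width = 0.5)
  expect_equal(dvh2$volume[dvh2$dose == 1.0], 1.0)
  expect_equal(dvh2$volume[dvh2$dose == 1.5], 0.5)
  expect_equal(dvh2$volume[dvh2$dose == 2.5], 0)

  # nonincreasing for arbitrary dose fields, starting at 1 at dose 0
  set.seed(6)
  d3 <- dose_from(array(runif(125, 0, 60), c(5, 5, 5)))
  m3 <- mask_from(as.matrix(expand.grid(1:5, 1:5, 1:5)), c(5, 5, 5))
  dvh3 <- compute_dvh(d3, m3)
  expect_equal(dvh3$volume[1], 1)
  expect_true(all(diff(dvh3$volume) <= 0))
  expect_error(compute_dvh(d3, mask_from(matrix(0, 0, 3), c(5, 5, 5))), "empty")
})

test_that("DVH statistics agree with the curve and the prescription", {
  m <- mask_from(as.matrix(expand.grid(1:2, 1:5, 1:5)), c(2, 5, 5))
  half <- array(0, c(2, 5, 5)); half[1, , ] <- 55; half[2, , ] <- 45
  dh <- dose_from(half, prescription = 50)
  st <- dvh_stats(dh, m, 50)
  expect_equal(st$mean_pct, 100)
  expect_equal(st$min_pct, 90)
  expect_equal(st$max_pct, 110)
  expect_equal(st$v100_pct, 50)

  du <- dose_from(array(50, c(2, 5, 5)), prescription = 50)
  stu <- dvh_stats(du, m, 50)
  expect_equal(unlist(stu), c(min_pct = 100, mean_pct = 100, max_pct = 100,
                              v100_pct = 100))
  # V100 equals the DVH curve evaluated at the prescription
  set.seed(11)
  dr <- dose_from(array(runif(50, 30, 70), c(2, 5, 5)))
  curve <- compute_dvh(dr, m, bin_width = 0.25)
  v100 <- dvh_stats(dr, m, 50)$v100_pct
  expect_equal(v100 / 100, curve$volume[which.min(abs(curve$dose - 50))])
  expect_error(dvh_stats(dr, m, 0), "prescription")
})

test_that("gamma is zero for identical plans and caps under gross offsets", {
  ref <- dose_from(smooth_dose_field(c(4, 8, 8), 1), spacing = c(2, 2, 2))
  g0 <- gamma_map(ref, ref, gamma_params())
  ev <- !is.na(g0$gamma)
  expect_true(all(g0$gamma[ev] == 0))
  expect_equal(g0$pass_rate, 100)

  # uniform +3%: dose term exactly 1 everywhere, no spatial remedy
  flat <- dose_from(array(10, c(4, 8, 8)), spacing = c(2, 2, 2))
  up3 <- flat; up3$data <- flat$data * 1.03
  g3 <- gamma_map(flat, up3, gamma_params(norm = 10))
  expect_equal(max(abs(g3$gamma[!is.na(g3$gamma)] - 1)), 0, tolerance = 1e-9)

  # single bumped reference voxel with flat evaluated field -> gamma exactly 1
  bump <- flat
  bump$data[2, 4, 4] <- 10 * 1.03
  gb <- gamma_map(bump, flat, gamma_params(norm = 10))
  expect_equal(gb$gamma[2, 4, 4], 1, tolerance = 1e-9)

  # uniform +6% -> capped at 2, pass rate 0
  up6 <- flat; up6$data <- flat$data * 1.06
  g6 <- gamma_map(flat, up6, gamma_params(norm = 10))
  expect_true(all(g6$gamma[!is.na(g6$gamma)] == 2))
  expect_equal(g6$pass_rate, 0)
})

test_that("gamma matches the exhaustive brute-force oracle", {
  p <- gamma_params()
  for (seed in 1:3) {
    ref <- smooth_dose_field(c(5, 7, 7), seed)
    ev <- smooth_dose_field(c(5, 7, 7), seed + 100)
    ev <- ref + 0.15 * (ev - mean(ev))
    sp <- c(2, 1.5, 1.5)
    refd <- dose_from(ref, spacing = sp)
    evd <- dose_from(ev, spacing = sp)
    g <- gamma_map(refd, evd, p)
    norm <- max(ref)
    gb <- brute_gamma(ref, ev, sp, p$dd / 100 * norm, p$dta,
                      p$threshold / 100 * norm, p$cap)
    expect_equal(g$gamma, gb, tolerance = 1e-6)
  }
  # 2D plane case
  ref2 <- smooth_dose_field(c(1, 10, 10), 9)
  ev2 <- ref2 * (1 + 0.02 * sin(seq_len(length(ref2)) / 7))
  r2 <- dose_from(ref2, spacing = c(1, 2, 2))
  e2 <- dose_from(array(ev2, dim(ref2)), spacing = c(1, 2, 2))
  g2 <- gamma_map(r2, e2, p, dims = "2D", plane = "axial", index = 1)
  gb2 <- brute_gamma(ref2, array(ev2, dim(ref2)), c(1, 2, 2),
                     p$dd / 100 * max(ref2), p$dta,
                     p$threshold / 100 * max(ref2), p$cap)
  expect_equal(g2$gamma, gb2, tolerance = 1e-6)
})

test_that("gamma is role-asymmetric but scale invariant", {
  ref <- dose_from(smooth_dose_field(c(4, 8, 8), 21), spacing = c(2, 2, 2))
  ev <- dose_from(smooth_dose_field(c(4, 8, 8), 22), spacing = c(2, 2, 2))
  p <- gamma_params()
  g_ab <- gamma_map(ref, ev, p)
  g_ba <- gamma_map(ev, ref, p)
  expect_false(isTRUE(all.equal(g_ab$gamma, g_ba$gamma)))

  # scaling both plans and the normalization leaves gamma unchanged
  p10 <- gamma_params(norm = max(ref$data) * 10)
  ref10 <- ref; ref10$data <- ref$data * 10
  ev10 <- ev; ev10$data <- ev$data * 10
  g10 <- gamma_map(ref10, ev10, p10)
  expect_equal(g10$gamma, gamma_map(ref, ev, gamma_params(norm = max(ref$data)))$gamma,
               tolerance = 1e-9)
})

test_that("dose resampling is trilinear and flags out-of-extent voxels", {
  ramp <- dose_from(array(rep(seq(0, 30, length.out = 16), each = 16),
                          c(4, 4, 16)), spacing = c(4, 4, 4))
  same <- resample_dose(ramp, ramp)
  expect_equal(same$data, ramp$data, tolerance = 1e-12)

  const <- dose_from(array(7, c(4, 6, 6)), spacing = c(3, 3, 3))
  tgt <- dose_from(array(0, c(7, 11, 11)), spacing = c(1.5, 1.5, 1.5))
  rc <- resample_dose(const, tgt)
  expect_true(all(abs(rc$data - 7) < 1e-12))

  # downsample then upsample a linear ramp: trilinear is exact on ramps
  coarse <- dose_from(array(0, c(4, 4, 8)), spacing = c(4, 4, 8),
                      prescription = 50)
  down <- resample_dose(ramp, coarse)
  up <- resample_dose(down, ramp)
  interior <- array(FALSE, dim(ramp$data)); interior[, , 2:14] <- TRUE
  expect_lt(max(abs(up$data[interior] - ramp$data[interior])), 1e-9)

  far <- dose_from(array(0, c(4, 4, 4)), origin = c(1000, 1000, 1000))
  expect_error(resample_dose(ramp, far), "overlap")
})

test_that("gamma and dose-difference histograms conserve counts and means", {
  ref <- dose_from(smooth_dose_field(c(4, 8, 8), 31), spacing = c(2, 2, 2))
  g0 <- gamma_map(ref, ref, gamma_params())
  h <- gamma_histogram(g0, bins = 256)
  expect_equal(sum(h$count), g0$n_evaluated)
  expect_equal(h$count[1], g0$n_evaluated)       # identical -> first bin

  flat <- dose_from(array(10, c(4, 8, 8)), spacing = c(2, 2, 2))
  up6 <- flat; up6$data <- flat$data * 1.06
  g6 <- gamma_map(flat, up6, gamma_params(norm = 10))
  h6 <- gamma_histogram(g6, bins = 256)
  expect_equal(h6$count[256], g6$n_evaluated)    # capped -> last bin

  dd0 <- dose_diff_histogram(ref, ref)
  expect_equal(dd0$mean, 0)
  shift <- ref; shift$data <- ref$data - 0.0118 * max(ref$data)
  dd <- dose_diff_histogram(ref, shift)
  expect_equal(dd$mean, -1.18, tolerance = 1e-9)
  dd2 <- dose_diff_histogram(ref, shift, bins = 64)
  expect_equal(dd$mean, dd2$mean)                # mean invariant to binning
  expect_equal(sum(dd$histogram$count), sum(ref$data >= 0.1 * max(ref$data)))
})

test_that("isodose contours recover analytic level sets", {
  # radially symmetric dose on one slice
  n <- 41; sp <- 2
  x <- ((1:n) - (n + 1) / 2) * sp
  r <- sqrt(outer(x^2, x^2, `+`))
  dose <- dose_from(array(rep(100 * exp(-r / 40), each = 1), c(1, n, n)),
                    spacing = c(1, sp, sp), origin = c(0, min(x), min(x)))
  lv <- 100 * exp(-30 / 40)  # analytic radius 30 mm
  ct <- isodose_contours(dose, lv, plane = "axial", index = 1)
  pts <- do.call(rbind, ct[[1]])
  rad <- sqrt(pts$u^2 + pts$v^2)
  expect_lt(max(abs(rad - 30)), sp)

  # uniform dose -> no interior contour, flagged
  uni <- dose_from(array(10, c(1, 8, 8)))
  cu <- isodose_contours(uni, 5, index = 1)
  expect_length(cu[["5"]], 0)
  expect_true("5" %in% attr(cu, "flagged"))

  # divergence of a plan with itself is zero
  expect_equal(unname(isodose_divergence(ct, ct)), 0)
})
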