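test_that("SNR matches hand arithmetic and scaling identities", {
  r <- vol_from(matrix(10, 8, 8))
  t1 <- vol_from(matrix(10 + c(1, -1), 8, 8))
  expect_equal(snr(r, t1), 10 * log10(100))            # 20 dB
  t2 <- vol_from(matrix(10 + 2 * c(1, -1), 8, 8))      # doubled error
  expect_equal(snr(r, t1) - snr(r, t2), 10 * log10(4))
  expect_identical(snr(r, r), Inf)
})

test_that("RMSE and MAE match hand arithmetic and the Jensen inequality", {
  r <- vol_from(matrix(0, 1, 2)); t <- vol_from(matrix(c(3, 4), 1, 2))
  expect_equal(rmse(r, t), sqrt(12.5))
  expect_equal(mae(r, t), 3.5)
  expect_equal(rmse(r, r), 0)
  expect_equal(mae(vol_from(matrix(5, 3, 3)), vol_from(matrix(12, 3, 3))), 7)
  set.seed(2)
  for (i in 1:8) {
    a <- vol_from(array(rnorm(60), c(3, 4, 5)))
    b <- vol_from(array(rnorm(60), c(3, 4, 5)))
    expect_lte(mae(a, b), rmse(a, b) + 1e-12)
  }
  expect_error(rmse(r, vol_from(matrix(0, 2, 2))), "share one grid")
})

test_that("SNR strictly decreases as independent noise grows", {
  ph <- make_phantom_ct(tiny_spec(14))
  body <- get_mask(ph$structures, "body")
  snr_at <- function(sigma) mean(vapply(1:4, function(s) {
    sp <- degradation_spec(cupping = 0, noise_sigma = sigma, streak_count = 0,
                           tissue_bias = c(), blur_fwhm = 0, seed = s)
    snr(ph$volume, degrade_to_cbct(ph$volume, ph$structures, sp), body)
  }, 0))
  v <- vapply(c(5, 15, 40), snr_at, 0)
  expect_true(all(diff(v) < 0))
})

test_that("checkerboard composites alternate blocks with a from the top-left", {
  a <- vol_from(matrix(1, 8, 8)); b <- vol_from(matrix(2, 8, 8))
  cb <- checkerboard(a, b, n = 2)
  expect_equal(cb$data[1, 1, 1], 1)   # top-left block from a
  expect_equal(cb$data[1, 1, 5], 2)
  expect_equal(cb$data[1, 5, 1], 2)
  expect_equal(cb$data[1, 5, 5], 1)
  expect_identical(checkerboard(a, a, 4)$data, a$data)

  wide <- vol_from(matrix(0, 16, 512))
  wb <- checkerboard(wide, vol_from(matrix(1, 16, 512)), n = 8)
  # block width 512 %/% 8 = 64 px: columns 1..64 from a, 65..128 from b
  expect_true(all(wb$data[1, 1, 1:64] == 0))
  expect_true(all(wb$data[1, 1, 65:128] == 1))
  expect_error(checkerboard(a, b, n = 16), "squares")
  expect_error(checkerboard(a, b, n = 1), "at least 2")
})

test_that("HU histograms conserve voxel counts", {
  v <- vol_from(array(7, c(4, 4, 4)))
  h <- hu_histogram(v, bins = 10, range = c(0, 10))
  expect_equal(sum(h$count), 64)
  expect_equal(sum(h$count > 0), 1)
  set.seed(5)
  v2 <- vol_from(array(rnorm(1000, 0, 200), c(10, 10, 10)))
  h2 <- hu_histogram(v2, bins = 64, range = c(-300, 300))  # clips tails
  expect_equal(sum(h2$count), 1000)
  expect_error(hu_histogram(v, range = c(5, 5)), "width")
})

test_that("CT/CBCT histogram overlap shrinks as noise grows", {
  ph <- make_phantom_ct(tiny_spec(18))
  body <- get_mask(ph$structures, "body")
  rng <- c(-1100, 600)
  h0 <- hu_histogram(ph$volume, 80, rng, body)
  overlap <- function(sigma) {
    sp <- degradation_spec(cupping = 0, noise_sigma = sigma, streak_count = 0,
                           tissue_bias = c(), blur_fwhm = 0, seed = 3)
    h <- hu_histogram(degrade_to_cbct(ph$volume, ph$structures, sp),
                      80, rng, body)
    sum(pmin(h$count, h0$count)) / sum(h0$count)
  }
  ov <- vapply(c(10, 40, 120), overlap, 0)
  expect_true(all(diff(ov) < 0))
})

test_that("organ HU statistics aggregate across subjects as sums of variances", {
  # constant organ -> mean exact, sd 0
  ph <- make_phantom_ct(tiny_spec(3))
  v <- ph$volume
  v$data[ph$structures$masks$liver] <- 54
  st <- organ_hu_stats(v, ph$structures, organs = "liver")
  expect_equal(st$per_subject$mean, 54)
  expect_equal(st$per_subject$sd, 0)

  # six subjects with per-subject variance 1 -> variability 6
  set.seed(8)
  subs <- lapply(1:6, function(i) {
    vv <- ph$volume
    x <- rnorm(sum(ph$structures$masks$liver))
    vv$data[ph$structures$masks$liver] <- 54 + (x - mean(x)) / sd(x)
    vv
  })
  st6 <- organ_hu_stats(subs, rep(list(ph$structures), 6), organs = "liver")
  expect_equal(st6$summary$variability, 6, tolerance = 1e-9)
  expect_equal(st6$summary$n_subjects, 6)

  empty <- ph$structures
  empty$masks$liver[] <- FALSE
  expect_error(organ_hu_stats(v, empty, organs = "liver"), "empty")
})
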