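test_that("Hausdorff distance matches enumeration on point-like masks", {
  d <- c(1, 5, 9)
  X <- mask_from(rbind(c(1, 3, 3)), d)
  Y <- mask_from(rbind(c(1, 3, 6)), d)          # 3 voxels apart in x, 1 mm each
  expect_equal(hausdorff(X, Y, "max"), 3)
  expect_equal(hausdorff(X, Y, "mean"), 3)
  expect_equal(hausdorff(X, X, "max"), 0)
  expect_equal(hausdorff(X, X, "mean"), 0)

  # X = {0,1}, Y = {0}: directed h(X,Y) = 1, h(Y,X) = 0 -> max mode 1
  X2 <- mask_from(rbind(c(1, 3, 3), c(1, 3, 4)), d)
  expect_equal(hausdorff(X2, X, "max"), 1)
  expect_equal(hausdorff(X2, X, "mean"), 0.25)  # (mean(0,1) + 0)/2

  expect_error(hausdorff(X, mask_from(matrix(0, 0, 3), d)), "empty")
})

test_that("Hausdorff respects anisotropic spacing and matches brute force", {
  set.seed(7)
  for (i in 1:5) {
    d <- c(6, 7, 8)
    sp <- c(2, 1.25, 0.8)
    X <- mask_from(cbind(sample(2:5, 12, TRUE), sample(2:6, 12, TRUE),
                         sample(2:7, 12, TRUE)), d, spacing = sp)
    Y <- mask_from(cbind(sample(2:5, 12, TRUE), sample(2:6, 12, TRUE),
                         sample(2:7, 12, TRUE)), d, spacing = sp)
    if (sum(X$mask) == 0 || sum(Y$mask) == 0) next
    expect_equal(hausdorff(X, Y, "max"), brute_hausdorff(X, Y, "max"),
                 tolerance = 1e-7)
    expect_equal(hausdorff(X, Y, "mean"), brute_hausdorff(X, Y, "mean"),
                 tolerance = 1e-7)
    expect_equal(hausdorff(X, Y, "max"), hausdorff(Y, X, "max"))  # symmetric
  }
})

test_that("Dice coefficient matches its formula and is translation invariant", {
  d <- c(4, 8, 8)
  A <- mask_from(rbind(c(2, 3, 3), c(2, 3, 4)), d)
  B <- mask_from(rbind(c(2, 3, 4), c(2, 3, 5)), d)
  expect_equal(dice(A, B), 0.5)                 # |X|=|Y|=2, overlap 1
  expect_equal(dice(A, A), 1)
  Dis <- mask_from(rbind(c(2, 6, 6)), d)
  expect_equal(dice(A, Dis), 0)
  expect_error(dice(mask_from(matrix(0, 0, 3), d),
                    mask_from(matrix(0, 0, 3), d)), "undefined")
  # translate both masks by one voxel -> unchanged
  A2 <- mask_from(rbind(c(2, 4, 3), c(2, 4, 4)), d)
  B2 <- mask_from(rbind(c(2, 4, 4), c(2, 4, 5)), d)
  expect_equal(dice(A2, B2), dice(A, B))
})

test_that("volume differences convert voxel counts to cm^3", {
  d <- c(12, 12, 12)
  base <- expand.grid(z = 3:8, y = 3:8, x = 3:8)
  X <- mask_from(as.matrix(base), d)                     # 216 voxels of 1 mm^3
  Y <- mask_from(as.matrix(base[1:116, ]), d)
  expect_equal(volume_diff(X, Y), 0.1)                   # 100 voxels = 0.1 cc
  expect_equal(volume_diff(X, X), 0)
  # 1000 extra 1 mm^3 voxels -> 1 cm^3
  big <- expand.grid(z = 1:10, y = 1:10, x = 1:10)
  expect_equal(volume_diff(mask_from(as.matrix(big), d),
                           mask_from(as.matrix(big[1:2, ]), d)),
               0.998)
  # dilation strictly increases volume
  ph <- make_phantom_ct(tiny_spec(2))
  ptv <- get_mask(ph$structures, "ptv")
  ns <- asNamespace("adaptsct")
  dil <- ptv
  for (ax in 1:3) for (by in c(-1, 1))
    dil$mask <- dil$mask | ns$shift_mask(ptv$mask, ax, by)
  expect_gt(volume_diff(ptv, dil), 0)
})

test_that("contour-set comparison reproduces the assessment table layout", {
  ph <- make_phantom_ct(tiny_spec(9))
  ref <- ph$structures
  tab <- compare_contour_sets(ref, list(self = ref))
  expect_true(all(tab$dice[tab$organ != "mean"] == 1))
  expect_true(all(tab$mean_hausdorff_mm == 0))
  expect_true(all(tab$delta_v_cc == 0))
  expect_true("mean" %in% tab$organ)

  # a missing organ is flagged, not dropped
  cand <- ref
  cand$masks$liver <- NULL
  tab2 <- compare_contour_sets(ref, list(broken = cand))
  expect_true(tab2$missing[tab2$organ == "liver"])
  expect_false(any(is.na(tab2$dice[tab2$organ == "spinal_canal"])))
})

test_that("small contour error beats a 7 mm registration surrogate organ by organ", {
  ph <- make_phantom_ct(fine_spec(25))
  sct_like <- make_ctdef_surrogate(ph$volume, ph$structures, 1, seed = 1)$structures
  ctdef_like <- make_ctdef_surrogate(ph$volume, ph$structures, 7, seed = 2)$structures
  tab <- compare_contour_sets(ph$structures,
                              list(sct = sct_like, ctdef = ctdef_like))
  for (o in setdiff(unique(tab$organ), "mean")) {
    ds <- tab$dice[tab$candidate == "sct" & tab$organ == o]
    dc <- tab$dice[tab$candidate == "ctdef" & tab$organ == o]
    expect_gt(ds, dc)
  }
})

test_that("mean Hausdorff grows monotonically with registration error", {
  ph <- make_phantom_ct(fine_spec(33))
  liver <- get_mask(ph$structures, "liver")
  hd <- vapply(c(0, 3, 7), function(err) {
    s <- make_ctdef_surrogate(ph$volume, ph$structures, err, seed = 4)
    hausdorff(liver, get_mask(s$structures, "liver"), "mean")
  }, 0)
  expect_equal(hd[1], 0)
  expect_true(all(diff(hd) > 0))
})
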