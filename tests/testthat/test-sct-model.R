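small_gen <- function(seed = 1) {
  build_generator(generator_spec(base_filters = 4, n_res = 1, depth = 1), seed)
}

test_that("slice preprocessing mirrors the published augmentation scheme", {
  paper_cfg <- train_config(crop_size = 256, work_size = c(480, 384),
                            crops_per_slice = 4)
  set.seed(1)
  slice <- matrix(-1000, 512, 512)
  slice[100:420, 120:400] <- rnorm(321 * 281, 40, 100)  # a body in free air
  patches <- preprocess_slice(slice, paper_cfg, seed = 3)
  expect_length(patches, 4)
  for (p in patches) expect_equal(dim(p), c(256, 256))
  # 1760 training slices at 4 crops each give the 7040-sample training set
  expect_equal(1760 * paper_cfg$crops_per_slice, 7040)

  # window endpoints map to exactly +-1
  cfg <- train_config(crop_size = 4)
  sl <- matrix(c(3000, -1000, 5000, -3000), 4, 4)
  pp <- preprocess_slice(sl, cfg, seed = 1)[[1]]
  expect_equal(pp[1, 1], 1)     # 3000 HU
  expect_equal(pp[2, 1], -1)    # -1000 HU
  expect_equal(pp[3, 1], 1)     # clipped from above
  expect_equal(pp[4, 1], -1)    # clipped from below

  # deterministic given seed
  p1 <- preprocess_slice(slice, paper_cfg, seed = 11)
  p2 <- preprocess_slice(slice, paper_cfg, seed = 11)
  expect_identical(p1, p2)
  expect_error(preprocess_slice(matrix(0, 100, 100), paper_cfg),
               "smaller")
})

test_that("an untrained generator is the identity and stays fully convolutional", {
  g <- small_gen(7)
  x <- matrix(rnorm(32 * 32, 0, 0.3), 32)
  expect_equal(generator_apply(g, x), x, tolerance = 1e-12)
  # different inference size than the (nominal) training patch
  x2 <- matrix(rnorm(48 * 20, 0, 0.3), 48, 20)
  expect_equal(dim(generator_apply(g, x2)), c(48, 20))
  expect_error(generator_spec(n_res = 0), "residual")
})

test_that("the patch discriminator emits a score map with a bounded receptive field", {
  d <- build_discriminator(discriminator_spec(), 2)
  expect_lt(d$receptive_field, 32)
  sm <- adaptsct:::discriminator_apply(d, matrix(rnorm(32 * 32), 32))
  expect_length(dim(sm), 3)
  expect_gt(prod(dim(sm)), 1)  # patch-level map, not a scalar
})

test_that("network gradients agree with finite differences", {
  ns <- asNamespace("adaptsct")
  set.seed(12)
  x <- array(rnorm(10 * 10 * 1), c(10, 10, 1))
  g <- small_gen(3)
  fw <- ns$gen_forward(g, x, keep = TRUE)
  gy <- array(rnorm(length(fw$y)), dim(fw$y))
  bw <- ns$gen_backward(g, fw, gy)
  eps <- 1e-6
  loss <- function(layers) {
    gg <- g; gg$layers <- layers
    sum(ns$gen_forward(gg, x)$y * gy)
  }
  for (li in c(1, 3, 5)) {  # encoder conv, residual block, decoder conv
    pn <- names(bw$grads[[li]])[1]
    for (k in sample(length(g$layers[[li]][[pn]]), 3)) {
      lp <- g$layers; lp[[li]][[pn]][k] <- lp[[li]][[pn]][k] + eps
      lm <- g$layers; lm[[li]][[pn]][k] <- lm[[li]][[pn]][k] - eps
      num <- (loss(lp) - loss(lm)) / (2 * eps)
      expect_lt(abs(num - bw$grads[[li]][[pn]][k]), 1e-5)
    }
  }
})

smoke_manifest <- function() {
  dir <- file.path(tempdir(), "smoke_ds")
  if (!file.exists(file.path(dir, "manifest.json")))
    generate_dataset(2, dir, spec = tiny_spec(), master_seed = 31)
  load_manifest(dir)
}

smoke_cfg <- function(epochs = 2, seed = 9) {
  train_config(epochs = epochs, crop_size = 16, crops_per_slice = 1,
               seed = seed, checkpoint_every = 1,
               gen = generator_spec(base_filters = 4, n_res = 1, depth = 1),
               disc = discriminator_spec(base_filters = 4, depth = 1))
}

test_that("training runs, logs finite losses and is seed-deterministic", {
  man <- smoke_manifest()
  ck <- train(man, smoke_cfg())
  expect_equal(nrow(ck$log), 2)
  expect_true(all(is.finite(as.matrix(ck$log))))
  expect_true(all(c("cycle", "adv", "grad", "idem", "tv") %in% names(ck$log)))

  ck2 <- train(man, smoke_cfg())
  expect_identical(ck$state$G_A$layers, ck2$state$G_A$layers)
  ck3 <- train(man, smoke_cfg(seed = 10))
  expect_false(identical(ck$state$G_A$layers, ck3$state$G_A$layers))
})

test_that("checkpoints save, reload and resume", {
  man <- smoke_manifest()
  cp <- file.path(tempdir(), "ck.rds")
  unlink(cp)
  ck2 <- train(man, smoke_cfg(epochs = 2), checkpoint_path = cp)
  expect_true(file.exists(cp))
  expect_true(file.exists(sub("\\.rds$", "_log.csv", cp)))
  back <- load_checkpoint(cp)
  expect_equal(back$config_hash, ck2$config_hash)
  # resuming to 3 epochs continues from the saved state
  ck3 <- train(man, smoke_cfg(epochs = 3), checkpoint_path = cp, resume = TRUE)
  expect_equal(nrow(ck3$log), 3)
  expect_equal(ck3$log[1:2, ], ck2$log[1:2, ], tolerance = 1e-12)
})

test_that("volume translation preserves grid, window and determinism", {
  man <- smoke_manifest()
  ck <- train(man, smoke_cfg())
  v <- read_volume(man$subjects[[2]]$cbct)
  out <- translate_volume(v, ck, "cbct2ct")
  expect_equal(dim(out), dim(v))
  expect_equal(out$spacing, v$spacing)
  expect_equal(out$origin, v$origin)
  expect_true(all(out$data >= -1000 & out$data <= 3000))
  out2 <- translate_volume(v, ck, "cbct2ct")
  expect_identical(out$data, out2$data)
  # the reverse direction uses the other generator
  rev <- translate_volume(v, ck, "ct2cbct")
  expect_false(identical(out$data, rev$data))
  expect_error(suppressWarnings(translate_volume(v, "no-such-file.rds")))
})

test_that("training rejects a discriminator that sees the whole patch", {
  man <- smoke_manifest()
  cfg <- smoke_cfg()
  cfg$disc <- discriminator_spec(base_filters = 4, depth = 2)  # RF 18 > 16
  expect_error(train(man, cfg), "receptive field")
})
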