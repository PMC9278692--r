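# Cycle-consistent unpaired CBCT<->CT translation model: two fully
# convolutional residual generators and two patch discriminators, trained
# with the five-term objective on randomly cropped axial patches.

#' Generator architecture specification
#'
#' Fully convolutional encoder / residual-transformer / decoder. Inference
#' size may differ from the training patch size.
#'
#' @param base_filters filters of the first convolution.
#' @param n_res number of residual blocks (>= 1).
#' @param depth number of stride-2 encoder stages (mirrored in the decoder
#'   as nearest-neighbour upsampling + convolution).
#' @param patch_size training patch side, informational.
#' @return object of class `generator_spec`.
#' @export
generator_spec <- function(base_filters = 8, n_res = 3, depth = 2,
                           patch_size = NULL) {
  if (n_res < 1) stop("need at least one residual block")
  if (depth < 0) stop("depth must be >= 0")
  structure(list(base_filters = as.integer(base_filters),
                 n_res = as.integer(n_res), depth = as.integer(depth),
                 patch_size = patch_size),
            class = "generator_spec")
}

#' Patch discriminator specification
#'
#' Outputs a patch-level real/fake score map; the receptive field must stay
#' smaller than the training patch.
#' @param base_filters filters of the first convolution.
#' @param depth number of stride-2 convolutions before the score map.
#' @return object of class `discriminator_spec`.
#' @export
discriminator_spec <- function(base_filters = 16, depth = 2) {
  structure(list(base_filters = as.integer(base_filters),
                 depth = as.integer(depth)),
            class = "discriminator_spec")
}

#' Build a generator with identity initialisation
#'
#' The network predicts a residual added to its input, and its final
#' convolution starts at zero, so an untrained generator is the identity
#' map.
#' @param spec a [generator_spec()].
#' @param seed integer weight seed.
#' @return object of class `sct_generator`.
#' @export
build_generator <- function(spec = generator_spec(), seed = 1L) {
  f <- spec$base_filters
  with_seed(seed, {
    layers <- list(layer_conv(3, 1, f, 1, 1, "relu"))
    ch <- f
    for (i in seq_len(spec$depth)) {
      layers <- c(layers, list(layer_conv(3, ch, ch * 2, 2, 1, "relu")))
      ch <- ch * 2
    }
    for (i in seq_len(spec$n_res)) layers <- c(layers, list(layer_res(ch)))
    for (i in seq_len(spec$depth)) {
      layers <- c(layers, list(layer_up(),
                               layer_conv(3, ch, ch %/% 2, 1, 1, "relu")))
      ch <- ch %/% 2
    }
    layers <- c(layers, list(layer_conv(3, ch, 1, 1, 1, "linear", gain = 0)))
    structure(list(layers = layers, spec = spec, seed = seed),
              class = "sct_generator")
  })
}

#' @rdname build_generator
#' @param dspec a [discriminator_spec()].
#' @export
build_discriminator <- function(dspec = discriminator_spec(), seed = 1L) {
  f <- dspec$base_filters
  with_seed(seed, {
    layers <- list(layer_conv(4, 1, f, 2, 1, "lrelu"))
    ch <- f
    for (i in seq_len(dspec$depth - 1)) {
      layers <- c(layers, list(layer_conv(4, ch, ch * 2, 2, 1, "lrelu")))
      ch <- ch * 2
    }
    layers <- c(layers, list(layer_conv(3, ch, 1, 1, 1, "linear")))
    rf <- 1L; sp <- 1L
    for (l in layers) {
      k <- dim(l$w)[1]
      rf <- rf + (k - 1L) * sp
      sp <- sp * l$stride
    }
    structure(list(layers = layers, spec = dspec, seed = seed,
                   receptive_field = rf),
              class = "sct_discriminator")
  })
}

pad_to_multiple <- function(m, mult) {
  h <- nrow(m); w <- ncol(m)
  ph <- (mult - h %% mult) %% mult
  pw <- (mult - w %% mult) %% mult
  if (ph == 0 && pw == 0) return(list(m = m, h = h, w = w))
  mm <- matrix(0, h + ph, w + pw)
  mm[1:h, 1:w] <- m
  if (ph > 0) mm[(h + 1):(h + ph), 1:w] <- m[h:(h - ph + 1), 1:w, drop = FALSE]
  if (pw > 0) mm[, (w + 1):(w + pw)] <- mm[, w:(w - pw + 1), drop = FALSE]
  list(m = mm, h = h, w = w)
}

gen_forward <- function(g, x, keep = FALSE) {
  fw <- net_forward(g$layers, x, keep)
  fw$x <- x
  fw$y <- x + fw$y
  fw
}

gen_backward <- function(g, fw, gy) {
  bw <- net_backward(g$layers, fw$caches, gy)
  bw$gx <- bw$gx + gy   # residual skip
  bw
}

#' Apply a generator to one normalized 2D patch or slice
#' @param g an `sct_generator`.
#' @param x matrix in normalized units.
#' @return matrix of the same size.
#' @export
generator_apply <- function(g, x) {
  x <- as_patch(x)
  mult <- 2L^g$spec$depth
  p <- pad_to_multiple(x, mult)
  xa <- array(p$m, dim = c(nrow(p$m), ncol(p$m), 1L))
  y <- gen_forward(g, xa, keep = FALSE)$y
  matrix(y, nrow(p$m), ncol(p$m))[seq_len(p$h), seq_len(p$w), drop = FALSE]
}

discriminator_apply <- function(d, x) {
  x <- as_patch(x)
  xa <- array(x, dim = c(nrow(x), ncol(x), 1L))
  net_forward(d$layers, xa, keep = FALSE)$y
}

#' Training configuration
#'
#' Paper-scale values (50 epochs, 256 crops from 480 x 384 working slices,
#' 4 crops per slice, HU window -1000..3000) remain reachable; the defaults
#' are desk scale: 32 x 32 crops from 64 x 64 phantom slices.
#'
#' @param epochs training epochs.
#' @param crop_size patch side drawn from each working slice.
#' @param work_size (H, W) the slice is cropped to before patch sampling
#'   (free air removed); `NULL` keeps the native slice size.
#' @param crops_per_slice random patches per slice per epoch.
#' @param hu_window HU range mapped linearly to `[-1, 1]`.
#' @param optimizer "adam" or "sgd".
#' @param lr generator learning rate.
#' @param lr_disc discriminator learning rate; the default trains the
#'   discriminators on a faster time scale than the generators, which at
#'   desk scale is needed for them to pick up the subtle (percent-level)
#'   CBCT artifact signal inside the wide HU window.
#' @param seed master seed for weights, shuffling and crop sampling.
#' @param checkpoint_every epochs between checkpoint writes.
#' @param gen,disc architecture specs.
#' @return object of class `train_config`.
#' @export
train_config <- function(epochs = 25, crop_size = 32, work_size = NULL,
                         crops_per_slice = 4, hu_window = c(-1000, 3000),
                         optimizer = c("adam", "sgd"), lr = 2e-3,
                         lr_disc = 3e-3, seed = 1L,
                         checkpoint_every = 10,
                         gen = generator_spec(), disc = discriminator_spec()) {
  optimizer <- match.arg(optimizer)
  if (hu_window[1] >= hu_window[2]) stop("HU window min must be < max")
  if (!is.null(work_size) && any(crop_size > work_size))
    stop("crop size must be <= working slice size")
  structure(list(epochs = as.integer(epochs), crop_size = as.integer(crop_size),
                 work_size = work_size, crops_per_slice = as.integer(crops_per_slice),
                 hu_window = as.numeric(hu_window), optimizer = optimizer,
                 lr = lr, lr_disc = lr_disc, seed = as.integer(seed),
                 checkpoint_every = as.integer(checkpoint_every),
                 gen = gen, disc = disc),
            class = "train_config")
}

hu_normalize <- function(m, window) {
  m <- pmin(pmax(m, window[1]), window[2])
  2 * (m - window[1]) / (window[2] - window[1]) - 1
}

hu_denormalize <- function(m, window) {
  window[1] + (m + 1) / 2 * (window[2] - window[1])
}

#' Preprocess one axial HU slice into normalized training patches
#'
#' Crops free air down to the configured working size (centred on the
#' non-air bounding box), clips to the HU window, rescales the window to
#' `[-1, 1]` and draws `crops_per_slice` random patches. Deterministic given
#' `seed`.
#'
#' @param slice 2D HU matrix.
#' @param cfg a [train_config()].
#' @param seed crop-sampling seed.
#' @return list of normalized `crop_size` x `crop_size` matrices.
#' @export
preprocess_slice <- function(slice, cfg, seed = cfg$seed) {
  if (!is.matrix(slice)) stop("slice must be a 2D matrix")
  ws <- cfg$work_size %||% dim(slice)
  if (any(dim(slice) < ws)) stop("slice smaller than the working size")
  if (any(ws < cfg$crop_size)) stop("slice smaller than the crop size")
  nonair <- which(slice > -400, arr.ind = TRUE)
  ctr <- if (nrow(nonair) > 0) colMeans(nonair) else dim(slice) / 2
  r0 <- pmin(pmax(round(ctr - ws / 2), 1), dim(slice) - ws + 1)
  work <- slice[r0[1]:(r0[1] + ws[1] - 1), r0[2]:(r0[2] + ws[2] - 1), drop = FALSE]
  work <- hu_normalize(work, cfg$hu_window)
  cs <- cfg$crop_size
  with_seed(seed, {
    lapply(seq_len(cfg$crops_per_slice), function(i) {
      i0 <- sample.int(ws[1] - cs + 1, 1)
      j0 <- sample.int(ws[2] - cs + 1, 1)
      work[i0:(i0 + cs - 1), j0:(j0 + cs - 1), drop = FALSE]
    })
  })
}

new_opt <- function(cfg, role = "gen") {
  list(kind = cfg$optimizer,
       lr = if (role == "disc") cfg$lr_disc %||% cfg$lr else cfg$lr,
       beta1 = 0.5, beta2 = 0.999, eps = 1e-8, t = 0L)
}

# one alternating generator/discriminator update on an unpaired patch pair
cyclegan_step <- function(st, a, b, w) {
  A <- array(a, dim = c(nrow(a), ncol(a), 1L))
  B <- array(b, dim = c(nrow(b), ncol(b), 1L))

  fwB <- gen_forward(st$G_A, A, keep = TRUE)     # fake CT
  fwRecA <- gen_forward(st$G_B, fwB$y, keep = TRUE)
  fwA <- gen_forward(st$G_B, B, keep = TRUE)     # fake CBCT
  fwRecB <- gen_forward(st$G_A, fwA$y, keep = TRUE)
  fwIdtB <- gen_forward(st$G_A, B, keep = TRUE)
  fwIdtA <- gen_forward(st$G_B, A, keep = TRUE)
  dfwB <- net_forward(st$D_B$layers, fwB$y, keep = TRUE)
  dfwA <- net_forward(st$D_A$layers, fwA$y, keep = TRUE)

  terms <- c(
    cycle = loss_cycle(A, fwRecA$y) + loss_cycle(B, fwRecB$y),
    adv = loss_adv(dfwB$y, role = "generator") +
      loss_adv(dfwA$y, role = "generator"),
    grad = loss_grad(A, fwB$y) + loss_grad(B, fwA$y),
    idem = mean(abs(fwIdtB$y - B)) + mean(abs(fwIdtA$y - A)),
    tv = loss_tv(fwB$y) + loss_tv(fwA$y))

  # ---- generator gradients --------------------------------------------------
  gRecA <- w["cycle"] * array(d_l1(fwRecA$y, A), dim = dim(A))
  bwRecA <- gen_backward(st$G_B, fwRecA, gRecA)
  gDB <- w["adv"] * d_lsgan_gen(dfwB$y)
  bwDB <- net_backward(st$D_B$layers, dfwB$caches, gDB)
  gFakeB <- bwRecA$gx + bwDB$gx +
    array(w["grad"] * d_loss_grad_out(A, fwB$y) +
            w["tv"] * d_loss_tv_out(fwB$y), dim = dim(A))
  bwGA1 <- gen_backward(st$G_A, fwB, gFakeB)

  gRecB <- w["cycle"] * array(d_l1(fwRecB$y, B), dim = dim(B))
  bwRecB <- gen_backward(st$G_A, fwRecB, gRecB)
  gDA <- w["adv"] * d_lsgan_gen(dfwA$y)
  bwDA <- net_backward(st$D_A$layers, dfwA$caches, gDA)
  gFakeA <- bwRecB$gx + bwDA$gx +
    array(w["grad"] * d_loss_grad_out(B, fwA$y) +
            w["tv"] * d_loss_tv_out(fwA$y), dim = dim(B))
  bwGB1 <- gen_backward(st$G_B, fwA, gFakeA)

  gIdtB <- w["idem"] * array(d_l1(fwIdtB$y, B), dim = dim(B))
  bwGA2 <- gen_backward(st$G_A, fwIdtB, gIdtB)
  gIdtA <- w["idem"] * array(d_l1(fwIdtA$y, A), dim = dim(A))
  bwGB2 <- gen_backward(st$G_B, fwIdtA, gIdtA)

  gradsGA <- add_grads(add_grads(bwGA1$grads, bwRecB$grads), bwGA2$grads)
  gradsGB <- add_grads(add_grads(bwGB1$grads, bwRecA$grads), bwGB2$grads)

  st$opt$t <- st$opt$t + 1L
  upA <- opt_update(st$G_A$layers, gradsGA, st$sG_A, st$opt)
  st$G_A$layers <- upA$layers; st$sG_A <- upA$state
  upB <- opt_update(st$G_B$layers, gradsGB, st$sG_B, st$opt)
  st$G_B$layers <- upB$layers; st$sG_B <- upB$state

  # ---- discriminator updates (fakes detached) -------------------------------
  for (side in c("A", "B")) {
    D <- if (side == "A") st$D_A else st$D_B
    real <- if (side == "A") A else B
    fake <- if (side == "A") fwA$y else fwB$y
    fr <- net_forward(D$layers, real, keep = TRUE)
    ff <- net_forward(D$layers, fake, keep = TRUE)
    dl <- loss_adv(ff$y, fr$y, role = "discriminator")
    bwr <- net_backward(D$layers, fr$caches, 2 * (fr$y - 1) / length(fr$y))
    bwf <- net_backward(D$layers, ff$caches, 2 * ff$y / length(ff$y))
    gD <- add_grads(bwr$grads, bwf$grads)
    st$optD$t <- st$opt$t
    if (side == "A") {
      up <- opt_update(st$D_A$layers, gD, st$sD_A, st$optD)
      st$D_A$layers <- up$layers; st$sD_A <- up$state
      terms["d_a"] <- dl
    } else {
      up <- opt_update(st$D_B$layers, gD, st$sD_B, st$optD)
      st$D_B$layers <- up$layers; st$sD_B <- up$state
      terms["d_b"] <- dl
    }
  }
  st$last_terms <- terms
  st
}

slices_from_manifest <- function(manifest, field) {
  vols <- lapply(Filter(function(s) s$role == "train", manifest$subjects),
                 function(s) read_volume(s[[field]]))
  if (length(vols) == 0) stop("manifest has no training subjects")
  unlist(lapply(vols, function(v)
    lapply(seq_len(dim(v$data)[1]), function(z) v$data[z, , ])),
    recursive = FALSE)
}

#' Train the CBCT->CT / CT->CBCT cycle-consistent model
#'
#' Alternates discriminator and generator updates over unpaired, randomly
#' cropped axial patches; both domains are shuffled independently each epoch
#' with seeds derived from `cfg$seed`. Writes a per-epoch loss log and is
#' resumable from its own checkpoints. Deterministic given the seed.
#'
#' @param manifest manifest list from [generate_dataset()] (or its path);
#'   CT patches come from the planning CTs, CBCT patches from the daily
#'   CBCTs of the training split.
#' @param cfg a [train_config()].
#' @param weights a [loss_weights()].
#' @param checkpoint_path where to save checkpoints (`NULL` = don't save).
#' @param resume continue from `checkpoint_path` if it exists.
#' @param verbose print per-epoch losses.
#' @return object of class `sct_checkpoint`: models, config, loss log.
#' @export
train <- function(manifest, cfg = train_config(), weights = loss_weights(),
                  checkpoint_path = NULL, resume = FALSE, verbose = FALSE) {
  if (is.character(manifest)) manifest <- load_manifest(manifest)
  ct_slices <- slices_from_manifest(manifest, "ct")
  cb_slices <- slices_from_manifest(manifest, "cbct")
  if (length(ct_slices) == 0 || length(cb_slices) == 0)
    stop("manifest must provide both CT and CBCT training volumes")

  if (!is.null(checkpoint_path) && resume && file.exists(checkpoint_path)) {
    st <- readRDS(checkpoint_path)$state
  } else {
    st <- list(G_A = build_generator(cfg$gen, derive_seed(cfg$seed, "GA")),
               G_B = build_generator(cfg$gen, derive_seed(cfg$seed, "GB")),
               D_A = build_discriminator(cfg$disc, derive_seed(cfg$seed, "DA")),
               D_B = build_discriminator(cfg$disc, derive_seed(cfg$seed, "DB")),
               opt = new_opt(cfg), optD = new_opt(cfg, "disc"),
               epoch = 0L, log = NULL)
    st$sG_A <- make_opt_state(st$G_A$layers)
    st$sG_B <- make_opt_state(st$G_B$layers)
    st$sD_A <- make_opt_state(st$D_A$layers)
    st$sD_B <- make_opt_state(st$D_B$layers)
    if (st$D_A$receptive_field >= cfg$crop_size)
      stop("discriminator receptive field must be smaller than the patch")
  }

  w <- loss_weights(unname(weights["cycle"]), unname(weights["adv"]),
                    unname(weights["grad"]), unname(weights["idem"]),
                    unname(weights["tv"]))
  while (st$epoch < cfg$epochs) {
    ep <- st$epoch + 1L
    a_pool <- unlist(lapply(seq_along(cb_slices), function(i)
      preprocess_slice(cb_slices[[i]], cfg, derive_seed(cfg$seed, "cropA", ep, i))),
      recursive = FALSE)
    b_pool <- unlist(lapply(seq_along(ct_slices), function(i)
      preprocess_slice(ct_slices[[i]], cfg, derive_seed(cfg$seed, "cropB", ep, i))),
      recursive = FALSE)
    a_pool <- with_seed(derive_seed(cfg$seed, "shufA", ep), sample(a_pool))
    b_pool <- with_seed(derive_seed(cfg$seed, "shufB", ep), sample(b_pool))
    n_it <- min(length(a_pool), length(b_pool))
    acc <- NULL
    for (it in seq_len(n_it)) {
      st <- cyclegan_step(st, a_pool[[it]], b_pool[[it]], w)
      if (any(!is.finite(st$last_terms)))
        stop(sprintf("NaN/Inf loss at epoch %d iteration %d: %s", ep, it,
                     paste(names(st$last_terms), signif(st$last_terms, 3),
                           sep = "=", collapse = " ")))
      acc <- if (is.null(acc)) st$last_terms else acc + st$last_terms
    }
    row <- c(epoch = ep, acc / n_it)
    st$log <- rbind(st$log, row)
    st$epoch <- ep
    if (verbose)
      message(paste(names(row), signif(row, 4), sep = "=", collapse = "  "))
    if (!is.null(checkpoint_path) &&
        (ep %% cfg$checkpoint_every == 0 || ep == cfg$epochs))
      save_checkpoint(st, cfg, w, checkpoint_path)
  }
  new_checkpoint(st, cfg, w)
}

new_checkpoint <- function(st, cfg, weights) {
  log <- as.data.frame(st$log)
  rownames(log) <- NULL
  structure(list(state = st, cfg = cfg, weights = weights, log = log,
                 config_hash = config_hash(list(cfg = cfg, weights = weights))),
            class = "sct_checkpoint")
}

save_checkpoint <- function(st, cfg, weights, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  saveRDS(new_checkpoint(st, cfg, weights), path)
  log <- as.data.frame(st$log); rownames(log) <- NULL
  utils::write.csv(log, sub("\\.rds$", "_log.csv", path), row.names = FALSE)
  invisible(path)
}

#' @rdname train
#' @param path checkpoint file written during training.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (!inherits(ck, "sct_checkpoint")) stop("not an adaptsct checkpoint")
  ck
}

#' Translate a volume slice-by-slice through a trained generator
#'
#' Each axial slice is normalized with the training HU window, passed at
#' full slice size through the fully convolutional generator, denormalized,
#' and clipped back to the window. Grid metadata is copied from the input.
#'
#' @param vol an [image_volume] in HU.
#' @param checkpoint an `sct_checkpoint` (or its file path).
#' @param direction "cbct2ct" or "ct2cbct".
#' @return an [image_volume].
#' @export
translate_volume <- function(vol, checkpoint,
                             direction = c("cbct2ct", "ct2cbct")) {
  direction <- match.arg(direction)
  if (is.character(checkpoint)) checkpoint <- load_checkpoint(checkpoint)
  if (!inherits(checkpoint, "sct_checkpoint"))
    stop("`checkpoint` must be an sct_checkpoint")
  g <- if (direction == "cbct2ct") checkpoint$state$G_A else checkpoint$state$G_B
  win <- checkpoint$cfg$hu_window
  out <- vol$data
  for (z in seq_len(dim(vol$data)[1])) {
    sl <- hu_normalize(vol$data[z, , ], win)
    ty <- generator_apply(g, sl)
    out[z, , ] <- pmin(pmax(hu_denormalize(ty, win), win[1]), win[2])
  }
  image_volume(out, vol$spacing, vol$origin)
}
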