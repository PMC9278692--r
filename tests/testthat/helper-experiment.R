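# The desk-scale directional experiment shared by the training-direction and
# acceptance tests: per seed, simulate a 4-subject cohort (3 train / 1 test),
# train the translation model, and measure image error, contour overlap and
# stand-in PTV dose deviation on the held-out subject. Cached per session so
# several tests can assert on one set of trained models.

.desk_cache <- new.env(parent = emptyenv())

desk_experiment <- function(seeds = c(1, 2, 3)) {
  key <- paste(seeds, collapse = "-")
  if (!is.null(.desk_cache[[key]])) return(.desk_cache[[key]])
  curve_ct <- ct_default()
  curve_obi <- obi_catphan504()
  rows <- lapply(seeds, function(seed) {
    dir <- file.path(tempdir(), sprintf("desk_%d", seed))
    man <- generate_dataset(4, dir, master_seed = 100 + seed)
    cfg <- train_config(epochs = 30, crop_size = 32, crops_per_slice = 2,
                        seed = seed)
    ck <- train(man, cfg)
    s <- Filter(function(x) x$role == "test", man$subjects)[[1]]
    truth <- read_volume(s$ct_daily)
    cbct <- read_volume(s$cbct)
    md <- read_structures(s$masks_daily)
    body <- get_mask(md, "body")
    sct <- translate_volume(cbct, ck, "cbct2ct")
    idem <- translate_volume(truth, ck, "cbct2ct")   # CT through G_CBCT->CT

    sct_st <- make_ctdef_surrogate(truth, md, 1,
                                   seed = derive_seed(seed, "sctc"))$structures
    ctdef_st <- read_structures(s$masks_ctdef)
    tab <- compare_contour_sets(md, list(sct = sct_st, ctdef = ctdef_st))

    ptv <- get_mask(md, "ptv")
    beams <- unlist(lapply(list(c(-60, 60), c(60, 180), c(180, 300)),
                           function(a) beam_arc(a[1], a[2], n = 4,
                                                iso = mask_centroid(ptv),
                                                width = 100, height = 70)),
                    recursive = FALSE)
    d_ct <- compute_dose(density_map(truth, curve_ct), beams, 50, ptv = ptv)
    d_cb <- compute_dose(density_map(cbct, curve_obi), beams, 50,
                         scale = d_ct$scale)
    d_sc <- compute_dose(density_map(sct, curve_ct), beams, 50,
                         scale = d_ct$scale)
    mp <- function(d) 100 * mean(d$data[ptv$mask]) / 50
    data.frame(
      seed = seed,
      mae_cbct = mae(truth, cbct, body),
      mae_sct = mae(truth, sct, body),
      rmse_cbct = rmse(truth, cbct, body),
      rmse_sct = rmse(truth, sct, body),
      mae_idem = mae(truth, idem, body),
      dice_sct = tab$dice[tab$candidate == "sct" & tab$organ == "mean"],
      dice_ctdef = tab$dice[tab$candidate == "ctdef" & tab$organ == "mean"],
      dev_cbct = abs(mp(d_cb) - mp(d_ct)),
      dev_sct = abs(mp(d_sc) - mp(d_ct)))
  })
  out <- do.call(rbind, rows)
  .desk_cache[[key]] <- out
  out
}

derive_seed <- adaptsct:::derive_seed
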