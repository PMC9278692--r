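# End-to-end orchestration of the assessment loop: simulate a phantom
# cohort, train the translation model, then evaluate image quality, anatomy
# preservation, HU accuracy and stand-in dosimetry, mirroring the structure
# of a clinical sCT assessment (quality -> anatomy -> HU -> dose).

#' Pipeline run configuration
#'
#' @param master_seed single integer seeding every stage (per-stage seeds
#'   are derived by fixed hashing).
#' @param n_subjects phantom cohort size.
#' @param out_dir working directory for datasets, checkpoints and reports.
#' @param phantom a [phantom_spec()] template.
#' @param degradation a [degradation_spec()].
#' @param ctdef_err residual error (mm) of the deformed-CT surrogate.
#' @param sct_contour_err residual error (mm) emulating independent
#'   re-contouring on the synthetic CT.
#' @param train a [train_config()].
#' @param weights a [loss_weights()].
#' @param prescription,fractions prescription dose (Gy) and fractions.
#' @param arcs list of `c(from, to)` gantry ranges approximating the VMAT
#'   partial arcs.
#' @param beams_per_arc static beams per arc.
#' @param gamma a [gamma_params()].
#' @return object of class `run_config`.
#' @export
run_config <- function(master_seed = 1L, n_subjects = 4L, out_dir = "adaptsct_run",
                       phantom = default_phantom_spec(),
                       degradation = degradation_spec(), ctdef_err = 7,
                       sct_contour_err = 1, train = train_config(),
                       weights = loss_weights(), prescription = 50,
                       fractions = 5,
                       arcs = list(c(-60, 60), c(60, 180), c(180, 300)),
                       beams_per_arc = 4, gamma = gamma_params()) {
  structure(list(master_seed = as.integer(master_seed),
                 n_subjects = as.integer(n_subjects), out_dir = out_dir,
                 phantom = phantom, degradation = degradation,
                 ctdef_err = ctdef_err, sct_contour_err = sct_contour_err,
                 train = train, weights = weights,
                 prescription = prescription, fractions = fractions,
                 arcs = arcs, beams_per_arc = beams_per_arc, gamma = gamma),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Scalar fields override the [run_config()] defaults; nested blocks
#' (`phantom`, `degradation`, `train`, `gamma`) override the corresponding
#' constructor arguments.
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  for (nm in c("master_seed", "n_subjects", "out_dir", "ctdef_err",
               "sct_contour_err", "prescription", "fractions", "beams_per_arc"))
    if (!is.null(y[[nm]])) args[[nm]] <- y[[nm]]
  if (!is.null(y$arcs)) args$arcs <- lapply(y$arcs, unlist)
  if (!is.null(y$degradation)) args$degradation <- do.call(degradation_spec, y$degradation)
  if (!is.null(y$train)) args$train <- do.call(train_config, y$train)
  if (!is.null(y$gamma)) args$gamma <- do.call(gamma_params, y$gamma)
  if (!is.null(y$weights)) args$weights <- do.call(loss_weights, y$weights)
  do.call(run_config, args)
}

stage_log <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf("[adaptsct %s] %s", format(Sys.time(), "%H:%M:%S"),
                               sprintf(fmt, ...)))
}

#' Simulate the phantom cohort of a run
#'
#' @param config a [run_config()] (or YAML path).
#' @param verbose log per-stage progress.
#' @return the dataset manifest, invisibly.
#' @export
cli_simulate <- function(config, verbose = TRUE) {
  if (is.character(config)) config <- read_run_config(config)
  stage_log(verbose, "simulating %d subjects into %s", config$n_subjects,
            config$out_dir)
  man <- generate_dataset(config$n_subjects,
                          file.path(config$out_dir, "dataset"),
                          spec = config$phantom,
                          degradation = config$degradation,
                          ctdef_err = config$ctdef_err,
                          master_seed = config$master_seed)
  stage_log(verbose, "wrote manifest with %d train / %d test subjects",
            man$n_train, man$n_test)
  invisible(man)
}

#' Train the translation model of a run
#' @inheritParams cli_simulate
#' @param manifest manifest (or path); default: the run's dataset.
#' @return an `sct_checkpoint`, also saved under `out_dir/checkpoint.rds`.
#' @export
cli_train <- function(config, manifest = NULL, verbose = TRUE) {
  if (is.character(config)) config <- read_run_config(config)
  manifest <- manifest %||% load_manifest(file.path(config$out_dir, "dataset"))
  cfg <- config$train
  cfg$seed <- derive_seed(config$master_seed, "train")
  stage_log(verbose, "training %d epochs (crop %d, optimizer %s)",
            cfg$epochs, cfg$crop_size, cfg$optimizer)
  ck <- train(manifest, cfg, config$weights,
              checkpoint_path = file.path(config$out_dir, "checkpoint.rds"),
              verbose = verbose)
  invisible(ck)
}

plan_beams <- function(config, iso) {
  unlist(lapply(config$arcs, function(a)
    beam_arc(a[1], a[2], n = config$beams_per_arc, iso = iso)),
    recursive = FALSE)
}

write_report_csv <- function(df, dir, name) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(df, file.path(dir, name), row.names = FALSE)
}

#' Evaluate trained synthetic CTs on the test split
#'
#' For every test subject: translates the CBCT to a synthetic CT; computes
#' image-quality metrics (SNR/RMSE/MAE vs the daily ground-truth CT, body
#' mask), contour-overlap metrics against the daily contours (sCT contours
#' emulated by a small re-contouring surrogate; deformed-CT surrogate as
#' comparator), organ HU statistics, electron-density maps, stand-in doses
#' for CT/CBCT/sCT/CTdef under one set of monitor units, DVH statistics,
#' and 2D/3D gamma versus the CTdef reference with gamma and percent
#' dose-difference histograms. Reports are written as CSV/JSON under
#' `out_dir/report`.
#'
#' @param config a [run_config()] (or YAML path).
#' @param manifest dataset manifest (or path); default: the run's dataset.
#' @param checkpoint trained `sct_checkpoint` (or path); default: the run's.
#' @param verbose log per-stage progress.
#' @return list of report tables, invisibly.
#' @export
cli_evaluate <- function(config, manifest = NULL, checkpoint = NULL,
                         verbose = TRUE) {
  if (is.character(config)) config <- read_run_config(config)
  manifest <- manifest %||% load_manifest(file.path(config$out_dir, "dataset"))
  checkpoint <- checkpoint %||% file.path(config$out_dir, "checkpoint.rds")
  if (is.character(checkpoint)) {
    if (!file.exists(checkpoint)) stop("evaluation stage: no trained checkpoint at ", checkpoint)
    checkpoint <- load_checkpoint(checkpoint)
  }
  test <- Filter(function(s) s$role == "test", manifest$subjects)
  if (length(test) == 0) stop("evaluation stage: manifest has no test subjects")
  curve_ct <- ct_default()
  curve_obi <- obi_catphan504()

  iq <- list(); contours <- list(); dstats <- list(); pair <- list()
  g2d <- list(); g3d <- list(); ddm <- list()
  vols_truth <- list(); vols_cbct <- list(); vols_sct <- list(); st_daily <- list()

  for (si in seq_along(test)) {
    s <- test[[si]]
    stage_log(verbose, "subject %s: loading volumes", s$id)
    truth <- read_volume(s$ct_daily)
    cbct <- read_volume(s$cbct)
    ctdef <- read_volume(s$ctdef)
    masks_daily <- read_structures(s$masks_daily)
    masks_ctdef <- read_structures(s$masks_ctdef)
    body <- get_mask(masks_daily, "body")

    stage_log(verbose, "subject %s: translating CBCT -> sCT", s$id)
    sct <- translate_volume(cbct, checkpoint, "cbct2ct")

    for (nm in c("cbct", "sct")) {
      img <- if (nm == "cbct") cbct else sct
      iq[[length(iq) + 1]] <- data.frame(
        subject = s$id, image = nm,
        snr_db = snr(truth, img, body), rmse_hu = rmse(truth, img, body),
        mae_hu = mae(truth, img, body))
    }

    # independent re-contouring on the sCT emulated by a small residual
    # misalignment of the daily contours
    sct_structs <- make_ctdef_surrogate(truth, masks_daily,
                                        config$sct_contour_err,
                                        seed = derive_seed(s$seed, "sctcontour"))$structures
    ct <- compare_contour_sets(masks_daily,
                               list(sct = sct_structs, ctdef = masks_ctdef))
    ct$subject <- s$id
    contours[[length(contours) + 1]] <- ct

    stage_log(verbose, "subject %s: stand-in dose calculation", s$id)
    iso <- mask_centroid(get_mask(masks_daily, "ptv"))
    ptv <- get_mask(masks_daily, "ptv")
    pbox <- which(ptv$mask, arr.ind = TRUE)
    fw <- (diff(range(pbox[, 3])) + 1) * truth$spacing[3] + 20
    fh <- (diff(range(pbox[, 1])) + 1) * truth$spacing[1] + 20
    beams <- lapply(plan_beams(config, iso), function(b) {
      b$width <- fw; b$height <- fh; b
    })
    ed_truth <- density_map(truth, curve_ct)
    dose_ct <- compute_dose(ed_truth, beams, config$prescription,
                            config$fractions, ptv = ptv)
    mk_dose <- function(vol, curve) compute_dose(density_map(vol, curve), beams,
                                                 config$prescription,
                                                 config$fractions,
                                                 scale = dose_ct$scale)
    doses <- list(ct = dose_ct, cbct = mk_dose(cbct, curve_obi),
                  sct = mk_dose(sct, curve_ct), ctdef = mk_dose(ctdef, curve_ct))

    rep <- dose_sensitivity_report(doses, masks_daily)
    rep$stats$subject <- s$id; rep$pairwise$subject <- s$id
    dstats[[length(dstats) + 1]] <- rep$stats
    pair[[length(pair) + 1]] <- rep$pairwise

    stage_log(verbose, "subject %s: gamma analysis", s$id)
    for (ev in c("cbct", "sct")) {
      for (pl in c("axial", "sagittal", "coronal")) {
        gm <- gamma_map(doses$ctdef, doses[[ev]], config$gamma, "2D", plane = pl)
        g2d[[length(g2d) + 1]] <- data.frame(subject = s$id, evaluated = ev,
                                             plane = pl, pass_rate = gm$pass_rate)
      }
      gm3 <- gamma_map(doses$ctdef, doses[[ev]], config$gamma, "3D")
      g3d[[length(g3d) + 1]] <- data.frame(subject = s$id, evaluated = ev,
                                           pass_rate = gm3$pass_rate)
      dd <- dose_diff_histogram(doses$ctdef, doses[[ev]])
      ddm[[length(ddm) + 1]] <- data.frame(subject = s$id, evaluated = ev,
                                           mean_diff_pct = dd$mean)
      if (si == 1) {
        rdir <- file.path(config$out_dir, "report")
        write_report_csv(gamma_histogram(gm3), rdir,
                         sprintf("gamma_histogram_%s_%s.csv", s$id, ev))
        write_report_csv(dd$histogram, rdir,
                         sprintf("dose_diff_histogram_%s_%s.csv", s$id, ev))
      }
    }

    vols_truth[[si]] <- truth; vols_cbct[[si]] <- cbct; vols_sct[[si]] <- sct
    st_daily[[si]] <- masks_daily
  }

  organ_tabs <- lapply(list(ct = vols_truth, cbct = vols_cbct, sct = vols_sct),
                       function(v) organ_hu_stats(v, st_daily))
  organ_summary <- do.call(rbind, lapply(names(organ_tabs), function(nm) {
    d <- organ_tabs[[nm]]$summary; d$image <- nm; d
  }))

  report <- list(image_quality = do.call(rbind, iq),
                 contours = do.call(rbind, contours),
                 organ_stats = organ_summary,
                 dose_stats = do.call(rbind, dstats),
                 dose_pairwise = do.call(rbind, pair),
                 gamma_2d = do.call(rbind, g2d),
                 gamma_3d = do.call(rbind, g3d),
                 dose_diff_mean = do.call(rbind, ddm))
  rdir <- file.path(config$out_dir, "report")
  for (nm in names(report)) write_report_csv(report[[nm]], rdir, paste0(nm, ".csv"))
  jsonlite::write_json(list(master_seed = config$master_seed,
                            config_hash = config_hash(config),
                            checkpoint_hash = checkpoint$config_hash),
                       file.path(rdir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  stage_log(verbose, "report written to %s", rdir)
  invisible(report)
}
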