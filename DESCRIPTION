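Package: adaptsct
Title: Synthetic-CT Assessment Pipeline for CBCT-Based Adaptive Radiotherapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale assessment loop for synthetic CT (sCT) generation in
    adaptive radiotherapy. Generates paired planning-CT / daily-CBCT abdominal
    digital phantoms with ground-truth structure masks, trains a small
    cycle-consistent unpaired CBCT-to-CT translation network with a five-term
    objective (cycle consistency, least-squares adversarial, gradient,
    idempotence, total variation), and evaluates the result with the metrics
    used in clinical sCT studies: SNR/RMSE/MAE image quality, Hausdorff and
    Dice contour overlap, HU histograms and organ statistics, piecewise-linear
    HU-to-electron-density calibration, a declared stand-in ray-trace dose
    engine, cumulative DVH statistics, and 2D/3D gamma analysis with
    brute-force-verified distance-to-agreement search.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    digest,
    stats,
    utils,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
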