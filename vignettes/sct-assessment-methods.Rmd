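---
title: "Methods: desk-scale assessment of synthetic CT for adaptive radiotherapy"
author: "adaptsct"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: desk-scale assessment of synthetic CT for adaptive radiotherapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem this package models

Daily cone-beam CT (CBCT) guides adaptive radiotherapy, but its Hounsfield
units (HU) are corrupted by scatter — cupping, streaks, noise, and
tissue-dependent intensity drift — so dose calculated directly on CBCT is
unreliable. The clinical workaround deforms the planning CT onto the daily
anatomy (CTdef); its weakness is residual registration error, worst where
anatomy changed topologically (new air pockets), with reported target
registration errors up to 7 mm. A cycle-consistent adversarial translation
network offers a third route: synthesize a CT-like image (sCT) from the
daily CBCT, keeping the daily anatomy while restoring planning-CT intensity
statistics.

`adaptsct` re-creates that entire assessment loop at desk scale: a seeded
digital-phantom cohort stands in for patients, a small CycleGAN stands in
for the clinical-scale network, and a declared ray-trace dose operator
stands in for the clinical dose engine. Every evaluation instrument —
SNR/RMSE/MAE, checkerboards, HU histograms, organ statistics, Hausdorff/Dice,
HU-to-electron-density calibration, DVHs, and 2D/3D gamma — is implemented
in full and verified against brute-force oracles, so the *logic* of the
clinical study (does the sCT beat the CBCT, and rival the CTdef?) can be
exercised end to end on a single CPU.

## The phantom cohort

`default_phantom_spec()` builds an abdominal phantom on a 32 x 64 x 64 grid
(4 x 3.5 x 3.5 mm voxels, 128 x 224 x 224 mm field of view): an elliptical
soft-tissue body (~40 HU), two lungs, liver, heart, two kidneys, a vertebral
column with spinal canal, aorta, and a spherical PTV lesion in the liver.
Organ HU means and standard deviations are the planning-CT organ statistics
reported for upper-abdominal SBRT patients (liver 54 +- 3, lungs -719 +- 11,
bones 349 +- 64, ...). Organs are painted in listed order (later wins), and
the returned masks are exclusive, so mask statistics recover the painted
values exactly up to sampling error.

Three companions derive from each planning phantom:

* **daily anatomy** — the spec re-generated with rigid organ shifts (liver,
  kidneys, PTV; sd ~2 mm, bounded at 8 mm), a smooth random residual
  deformation (3 mm amplitude, 50 mm correlation length), and an anterior
  bowel gas pocket (7-10 mm radius) carved to -1000 HU. This is the ground
  truth all metrics use.
* **daily CBCT** — the daily anatomy degraded by per-tissue HU drift, a
  radially increasing cupping depression (40 HU at the body centre), 2 mm
  FWHM in-plane blur, 25 HU Gaussian noise, and 12 Gaussian-profile streak
  ridges (60 HU scale, alternating sign), all confined to the body. The
  tissue-drift defaults are calibrated so the *net* organ-mean drift
  (bias + cupping + blur) lands on the published CBCT organ statistics
  (heart 36 -> ~74 HU, lungs -719 -> ~-600 HU, liver 54 -> ~38 HU); nothing
  else in the published description quantifies artifact magnitudes, so
  magnitudes beyond the organ means are package choices held fixed across
  all experiments.
* **CTdef surrogate** — the daily phantom warped by a smooth random field
  whose maximum displacement is exactly the requested registration error
  (7 mm by default), contours included. This is a controlled stand-in for a
  deformable registration product, not a registration algorithm.

What the generator deliberately does **not** emulate: projection-domain
physics (scatter kernels, beam hardening), realistic organ shapes/texture
correlations, couch/fiducial structures, breathing motion blur beyond the
isotropic kernel, and CBCT field-of-view truncation (available but off by
default). Passing the package's directional experiments therefore shows the
assessment machinery behaves correctly under the modelled statistics — not
that any specific network will succeed on clinical data.

## The translation model

Two fully convolutional generators (CBCT->CT and CT->CBCT) and two patch
discriminators are trained on unpaired 32 x 32 crops of normalized axial
slices (HU window [-1000, 3000] mapped to [-1, 1] — the window kept wide
deliberately, because abdominal fields include lung). Each generator is an
encoder (stride-2 convolutions), three residual blocks, and a
nearest-neighbour-upsampling decoder, predicting a *residual* added to its
input with a zero-initialised output convolution — an untrained generator is
exactly the identity, which anchors inference and lets training start from
"change nothing".

The objective is the five-term weighted sum (weights 10/1/1/1/1):

* cycle consistency `|x - G'(G(x))|` — anatomy must survive a round trip;
* least-squares adversarial loss on patch score maps — realism;
* gradient loss (difference of finite-difference gradient magnitudes) —
  edge preservation;
* idempotence loss `|G(y) - y|` for `y` already in the target domain;
* anisotropic total variation — suppress spurious texture.

Numerical choices worth knowing:

* **Optimizer.** Adam (beta1 = 0.5) by default, with plain SGD selectable.
  The training description this mirrors says only "stochastic gradient
  descent"; un-tuned constant-step SGD does not converge reliably at this
  scale, so the adaptive-moment variant is the default.
* **Two time scales.** `lr = 2e-3` for generators, `lr_disc = 3e-3` for
  discriminators (16 base filters). The artifact signal is ~1% of the
  normalized window; discriminators trained at the generator rate collapse
  to a constant 0.5 score and supply no gradient. Rates were chosen on a
  pilot cohort by held-out MAE.
* **Desk-scale patch size.** 32 x 32 crops from 64 x 64 slices keep the
  random-crop augmentation geometry of the full-scale recipe (256 x 256
  from 480 x 384) while fitting a CPU. The full-scale values remain
  reachable through `train_config()`.
* **Determinism.** All weight init, cropping and shuffling seeds derive
  from one master seed by fixed hashing; training twice with one seed is
  bit-identical, and slice-wise inference is deterministic and
  metadata-preserving.
* **Divergence.** A non-finite loss aborts immediately with the epoch,
  iteration and per-term values.

## Calibration and the stand-in dose operator

`hu_to_density()` interpolates piecewise-linearly between the knots of a
calibration curve and clamps beyond the end knots. Two curves ship with the
package: the measured on-board-imager Catphan-504 table (six insert
materials, the water anchor, and the standard-curve maximum knot) and a
generic CT-simulator-style default that is explicitly synthetic — the
clinical planning-CT curve is published only graphically.

The dose operator is a declared stand-in, not a clinical algorithm: each
beam deposits `weight * exp(-mu * radiological_depth)` inside a divergent
rectangular field (mu = 0.005/mm water-equivalent; depth integrated by
fixed-step trilinear sampling at half the smallest voxel spacing), summed
over beams; VMAT arcs become fans of equally spaced static beams. It is
deterministic, linear in beam weights, and monotone in radiological depth —
exactly the properties needed to expose HU errors as dose errors. Absolute
dose values mean nothing clinically; only comparisons between plans
computed with the same monitor units do (the CT plan's scale factor is
imposed on the CBCT/sCT/CTdef plans).

## Gamma analysis

`gamma_map()` implements the Low distance-to-agreement formulation: for
every reference voxel above the low-dose threshold (10% of the
normalization dose; global normalization to the reference maximum by
default, matching the cited formulation), the minimum over candidate
positions of `sqrt(dist^2/dta^2 + doseDiff^2/dd^2)` with 3%/2 mm defaults,
the evaluated dose interpolated trilinearly on a lattice refining the grid
to <= dta/3 spacing, values capped at 2. The search is restricted to a
radius of 3 x dta, which is *exact* under the cap: beyond `cap * dta` the
distance term alone exceeds the cap. The test suite keeps an exhaustive
brute-force minimiser (no radius, no pruning) and requires agreement to
1e-6 on small grids. 2D gamma operates on the orthogonal plane through the
isocenter; voxels marked invalid by dose resampling are excluded from both
sides of the pass rate.

## The directional experiment

The clinical result this package mirrors is an *ordering*, not a number:
sCT image error below CBCT image error; sCT contours closer to the daily
contours than a 7 mm-error CTdef; sCT dose deviation from ground truth
below CBCT dose deviation. The acceptance suite re-runs that experiment
from scratch at desk scale — a 4-subject cohort (3 train / 1 test per
seed), 30 epochs of training at three independent seeds (~5 minutes per
seed on one CPU), then MAE, mean-organ Dice, and mean-PTV-dose deviations
under the stand-in engine. sCT contours are emulated by a 1 mm residual
surrogate (independent re-contouring noise), against the 7 mm CTdef
surrogate, mirroring how the clinical comparison was contoured on each
image. Problem sizes (64 x 64 phantoms, 4 subjects, 30 epochs) are the
package's chosen desk scale; the clinical-scale tables (patient SNR/RMSE/
MAE, 94-100% gamma pass rates) are not reproducible from phantoms and are
used only for these directional properties.

## Known limitations

* The generator cannot fully remove stochastic noise: cycle consistency
  penalises any change the reverse generator cannot invert, so desk-scale
  MAE gains come mostly from the invertible components (cupping, tissue
  drift, streak suppression). This is a real property of cycle-consistent
  training, visible here because the phantom's noise is exactly known.
* Exact supplementary loss formulas of the mirrored recipe are not printed
  in its main text; the gradient/idempotence/TV forms here are the simplest
  ones matching their stated purposes, each isolated behind one function so
  alternates can be swapped.
* The dose operator has no buildup region, scatter kernel or MLC model;
  gamma pass rates computed on it exercise the gamma code, not clinical
  plan quality.
* Whether the mirrored assessment masked its image metrics to the body is
  unstated; this package defaults to the body mask (air otherwise dominates
  every metric) with whole-grid mode available.
* The segment-variability column is interpreted as the sum over subjects of
  per-subject HU variances; a pooled-SD reading would differ by a constant
  factor but not change any ordering.
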