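---
title: "Methods: simulation-backed hyperspectral browning assessment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation-backed hyperspectral browning assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blanchspec)
```

## The problem and the modelling approach

Blanching fresh-cut potato at 80 °C is meant to inactivate polyphenol
oxidase (PPO), the enzyme that oxidises phenolic compounds (TPC) into brown
pigments. Slices blanched too briefly look fine immediately after processing
but brown during storage, and the browning pattern depends on where residual
enzyme survives within the tissue. Hyperspectral imaging in the 600–1000 nm
VIS/NIR window, calibrated against destructive bench assays through partial
least squares regression (PLSR), can estimate PPO activity (U/g fresh
weight) and total phenolic content (mg gallic-acid equivalents/100 g) per
sample and — because the fitted model is affine in the spectrum — per pixel.

`blanchspec` implements that analysis chain and, because no public
instrument data exist for this design, pairs it with a forward simulator
that generates raw frame stacks with known per-pixel ground truth. The
simulator is first-class, tested code: it defines the study conditions under
which every downstream claim in the test suite is evaluated.

## Forward model of a simulated scene

A scene is a slice (HSI mode) or thin section (HMI mode) imaged at `B`
wavelengths. True reflectance follows a linear mixing model,

$$R(x, y, \lambda) = m(\lambda) + a_p\,\mathrm{PPO}(x,y)\,c_p(\lambda)
  + a_t\,\mathrm{TPC}(x,y)\,c_t(\lambda),$$

where `m` is the bulk tissue matrix spectrum, `c_p`, `c_t` are chromophore
endmembers, and `a_p`, `a_t` (negative) convert concentration into
absorption-like reflectance loss. All endmembers are Gaussian-feature
spectra (`make_endmember_spectrum()`): the HSI matrix carries peaks at 705
and 800 nm and valleys at 750 and 985 nm; the HMI matrix, sharper peaks at
716 and 812 nm and a valley near 784 nm — the features each modality
resolves in mean spectra of this material. The PPO chromophore has features
at 705 and 812 nm and the TPC chromophore at 782 and 807 nm, so that
beta-coefficient wavelength selection has a known answer.

Raw counts add the sensor chain:

$$\mathrm{raw} = d + I(x,y)\,R\,g + \varepsilon, \qquad
  \mathrm{white} = d + I(x,y)\,g + \varepsilon, \qquad
  \mathrm{dark} = d + \varepsilon,$$

with dark current `d`, white-reference gain `g`, Gaussian noise
`ε ~ N(0, (noise_sd · g)²)`, and a multiplicative illumination surface
`I(x, y)` — a fixed low-order polynomial rescaled to exactly
`[1 − A, 1 + A]`, chosen over a random surface because it is reproducible
and analytically checkable. Because white shares the illumination surface
with raw, two-point calibration
`(raw − dark)/(white − dark)` cancels it exactly; with all defects switched
off the round trip is exact to machine precision, which the tests assert at
`1e−10`.

### Geometry and concentration fields

HSI scenes place a disc of radius `slice_radius_fraction · min(H, W)/2`
(default 0.9) divided into concentric zones at fractional radii
0.35/0.75/0.85/1.0 — pith, perimedullary zone, vascular ring, cortex. HMI
scenes are full-frame tissue (a 20 × 20 mm section has no slice boundary in
a microscope's field of view) labelled as perimedullary material, the region
sections are taken from, with thin high-reflectance cell-wall ridges
rendered as a seeded periodic lattice; HMI also uses a finer 4 nm grid (101
bands) against HSI's 5 nm (81 bands), reflecting the tunable filter's 3–8 nm
resolution. Band counts and frame sizes are not reported for the physical
instruments; 64 × 64 frames and these grids are this package's choices,
small enough that the repeated-simulation studies in the tests and the
acceptance script complete in minutes while leaving ≥ 3000 foreground pixels
per scene.

PPO follows first-order thermal inactivation,
`PPO(x,y) = P_0(zone) · exp(−k t)` with `k = 0.35/min`, so the 0/2/4/6/10
min design spans residual activities of 100 % down to 3 % — the progressive
decrease seen in bench assays of this design, with substantial residual
activity at 2–4 min. TPC is the per-zone baseline without a time trend. Zone
baselines (PPO 40/65/55/45 U/g; TPC 60/95/80/70 mg/100 g, perimedullary
highest) give bulk values in the ranges bench assays report for this
material. Both fields are modulated by a smooth multiplicative
heterogeneity field: white noise filtered with a separable normalized
Gaussian kernel of scale `min(H, W)/8`, then standardized — tissue
heterogeneity is smooth, not pixel-independent. Because the field derives
from the scene seed and not from blanching time, PPO is pointwise
non-increasing in time at fixed seed, a property the tests check.

### What the simulator emulates — and what it does not

Emulated: blanching-dependent chemistry, tissue zonation, the modality's
characteristic spectral features, dark current, smooth uneven illumination,
i.i.d. Gaussian sensor noise, assay measurement error (multiplicative,
CV 0.05), and per-sample biological variation (lognormal factors, SD 0.15,
on both baselines). Not emulated: scattering and radiative transfer,
specular highlights, starch gelatinisation mechanics, wavelength-dependent
illumination colour, detector nonlinearity, or spatially correlated sensor
noise. Passing tests therefore demonstrate the correctness and internal
consistency of the analysis chain under a known linear forward model — they
do not certify performance on physical potatoes, where R²p near 0.7–0.9 is
the realistic regime rather than the ~0.99 these clean simulations yield.

## Preprocessing decisions

* **ROI rule** (`pca_roi()`): pixels are scored on the first principal
  component of the mean-centred spectra, thresholded by Otsu's method, the
  mask oriented so the selected class has the higher broadband reflectance,
  and the largest connected component kept. The vendor software's "PCA
  ROI" feature is not algorithmically documented; this is the simplest
  reproducible reading, and it recovers the true foreground to ≥ 99 % at
  default noise.
* **No scatter correction by default**: models are fit on raw reflectance;
  SNV (`apply_snv()`, sample n−1 SD) is available behind a flag. Reflectance
  is *not* clipped to [0, 1] — values slightly above 1 occur near the white
  level under noise and clipping would bias band means.
* **Calibration floor** 1e−6 on `white − dark` avoids division blow-ups at
  dead pixels; if more than 1 % of elements sit at the floor a warning is
  raised rather than an error, since isolated dead pixels are normal.

## Chemometrics decisions

* **NIPALS PLS1 with mean centring only** — no variance scaling — the
  dominant convention for reflectance spectra, where the band scale is
  already common.
* **Split and folds**: 75/25 random calibration/prediction split
  (`round(0.75 N)` training samples); the random 10-fold cross-validation
  runs on the calibration portion only. Folds are drawn once per run from a
  sub-stream of the master seed; fold sizes differ by at most one.
* **Component selection**: the RMSECV curve is computed from pooled
  out-of-fold predictions; the chosen count is the *smallest* `k` whose
  RMSECV lies within 5 % (`tie_tol`) of the minimum. A strict argmin was
  tried first and rejected: gaps of 1–3 % between adjacent `k` are within
  CV noise, and the extra component can inflate `||β||` by an order of
  magnitude, which matters later — pixel-wise prediction multiplies
  per-pixel sensor noise by `||β||`, and the inflated models degraded
  map–truth correlation from ≈ 0.9 to ≈ 0.13 while sample-level R²p barely
  moved. The 5 % window is a conventional parsimony margin, not a fitted
  constant.
* **R² definition**: `1 − SS_res/SS_tot` with the mean of the evaluated
  subset, penalising bias (not the squared Pearson correlation). On a test
  set with zero response variance R²p is reported as missing with a
  warning.
* **RPD** uses the sample (n−1) SD of the *calibration* reference values
  divided by RMSEP.
* **Selection optimism**: because `k` is chosen at the RMSECV minimum, the
  pooled cross-validated R² on pure-noise responses can be marginally
  positive (a few hundredths); at any fixed `k` it is non-positive, which
  is how the no-spurious-skill property is tested.
* **Significant wavelengths** are local extrema of `|β|` (endpoints compared
  to their single neighbour) at least `min_rel_height` (default 0.2) of the
  global maximum. On simulated HSI data the two PPO chromophore features at
  705 and 812 nm are recovered within one band in ≥ 90 % of repeated runs;
  at a 0.5 threshold they are typically the only survivors.

## Mapping and colour decisions

* **Clip policy**: pixel spectra lie outside the calibration hull, so
  pixel predictions are clipped to the training-response range by default
  (`clip_policy = "train_range"`); `"none"` is available and is what the
  linearity identity — spatial mean of predictions equals prediction of the
  mean spectrum, exact for an affine model — is asserted on.
* **Display range** is the 1st–99th percentile of masked predictions,
  robust to hot pixels; it is a presentation choice only and is annotated in
  the PNG's JSON sidecar. Background renders neutral grey and is stored as
  `NA`, never 0.
* **ΔE (CIE76)** is computed per replicate against that replicate's own 0 h
  colour and then averaged per (blanching, storage) group. This is the only
  reading under which group ΔE means ± SD are well defined, and it explains
  why a published per-replicate mean (10.8 for unblanched slices at 24 h)
  differs from the 10.68 computable from the group-mean colours: the mean of
  norms is never smaller than the norm of means. Conversions use sRGB with
  the D65 white point; an affine colour-board correction
  (`fit_colour_correction()`) absorbs device deviation upstream.

## Numerical and reproducibility choices

* One master seed per run; every stochastic stage (heterogeneity fields,
  rendering, assays, per-sample variation, split, folds) draws from its own
  derived sub-stream, so adding a stage never shifts another stage's
  stream, and all derived seeds stay below 2³¹.
* NIPALS stops early (with a warning when components were already
  extracted, an error otherwise) if `||X'y||` falls below 1e−12 — the
  response is orthogonal to the deflated predictors.
* Degenerate inputs are rejected with named errors: constant cubes ("no
  contrast"), empty masks, zero-variance spectra for SNV, non-increasing
  zone radii, coplanar colour patches, ENVI headers lacking wavelengths.
* ENVI I/O is little-endian, data types float32/float64, interleaves
  BIL/BSQ/BIP; wavelengths are serialized at 17 significant digits.

## Problem sizes used by the tests

The repeated-simulation studies use 60 samples per dataset and 20 master
seeds (HSI, 64 × 64 × 81 cubes); ROI and mapping checks use single scenes;
the Monte-Carlo split-uniformity check uses 4000 splits of 100 samples.
These sizes were chosen as the smallest at which the stochastic properties
stabilise; the whole suite runs in about two minutes.

## Known limitations

* Linear mixing only; no scattering physics, so HMI's short-path advantage
  over HSI is not reproduced — in these simulations both modalities perform
  similarly.
* The PCA ROI uses one component and a global Otsu threshold; heavily
  vignetted raw frames would need calibration before segmentation (the
  pipeline always calibrates first).
* TPC has no blanching-time trend in the simulator, so models predicting it
  lean entirely on the chromophore signal and per-sample variation.
* `significant_wavelengths()` reports grid positions of extrema; with 5 nm
  spacing a feature centred between bands lands on the nearer band.
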