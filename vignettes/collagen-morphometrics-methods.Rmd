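---
title: "Methods: collagen morphometrics and prognostic scoring from SHG images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: collagen morphometrics and prognostic scoring from SHG images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`collascore` quantifies collagen fiber architecture in 12-bit
second-harmonic-generation (SHG) tiles and evaluates its prognostic value
for overall survival (OS). This vignette documents the models, the
tunable parameters and the numerical choices, and states what the
synthetic-data generators do and do not emulate.

## Segmentation model

Pixel intensities are modelled as a univariate Gaussian mixture; the
collagen mask is the union of all components except the dimmest one.
The fit uses only the intensity histogram — no spatial or texture
terms — which assumes collagen is distinguished from background by
brightness alone. EM runs on the (at most 4096-bin) histogram, which
makes fitting a 512×512 tile effectively instantaneous and exactly
equivalent to fitting the flattened pixel vector.

Numerical choices:

* **Initialization**: k-means on the pixel intensities with a fixed
  seed; EM is deterministic afterwards.
* **Convergence**: relative log-likelihood change below `1e-4`,
  at most 200 iterations; non-convergence returns the model with
  `converged = FALSE` and a warning.
* **Variance floor** of 0.25 squared intensity units: on (near-)discrete
  intensity distributions an unfloored component collapses onto a single
  value and the likelihood diverges. With the floor, a 50/50 two-point
  image is recovered with component means within ±1 intensity unit.
* **Separation guard** (`min_separation = 3`): with `n_components = 2`,
  a tile containing no collagen still yields two components — they split
  the background noise roughly in half, which would label ~40% of a pure
  background tile as collagen. The guard declares the mask empty when
  the Fisher-type separation
  `(mu_fg − mu_bg) / sqrt((var_fg + var_bg)/2)` is below 3. Typical
  collagen/background separations on our phantoms are an order of
  magnitude above the guard; pure-noise splits are around 1.
* **Small-object removal** (`min_object_px = 5`): isolated specks
  destabilize skeletonization and contribute no tractable fibers.

With two components, maximum-posterior assignment is equivalent to a
single intensity threshold; the test suite verifies this by brute force
over all 4096 intensity values.

## Skeletonization and the fiber network

The mask is thinned with Zhang–Suen thinning followed by a sequential
removal of (8,4)-simple pixels. The second pass exists because
Zhang–Suen leaves diagonal strokes as two-pixel staircases; sequential
simple-point deletion reduces them to unit width without changing
topology (a pixel is only deleted if its foreground neighbours form one
8-connected component *and* it has a 4-adjacent background pixel — the
second condition protects e.g. the centre of a plus-sign from opening a
hole).

The distance map reports, for each skeleton pixel, the Euclidean
distance transform of the mask minus half a pixel, i.e. the distance
from the pixel centre to the mask boundary: a solid bar 5 px tall has
medial-axis distance 2.5 px and local width 5 px.

The skeleton graph (8-neighbour adjacency) is decomposed into fibers:

* pixels with ≥3 neighbours form **junction clusters** (adjacent
  junction pixels merged; represented by the pixel nearest the cluster
  centroid);
* maximal chains between junctions/endpoints are traced into ordered
  vertex lists;
* **spur pruning**: chains shorter than `spur_length = 5` px dangling
  off a junction are artefacts of thinning and are removed;
* **branch joining** (`junction_mode = "join"`, the default): at each
  junction, the two branches whose directions continue most smoothly are
  merged into one fiber when the deviation from straight continuation is
  below `continuation_angle = 45°`. Ties are broken toward the smaller
  deviation, then toward the longer combined fiber. Branch directions
  are estimated from the 4th pixel into each chain. With
  `junction_mode = "split"` every chain ends at junctions; this changes
  the scale of fiber number and length (an X is 2 fibers when joining,
  4 when splitting) and is exposed because either reading of "a fiber"
  is defensible;
* fibers shorter than `min_fiber_length = 10` px are discarded.

A **cross-link** is a vertex shared by at least two fibers; shared
coordinates closer than 2 px are merged into one cross-link (junction
clusters on thick crossings would otherwise be counted several times).
On small scenes the detected set is tested against an independent
brute-force scan over all fiber pairs.

Known geometric biases, inherent to pixel-grid skeletons and documented
rather than hidden:

* path length is the sum of unit/diagonal vertex steps, which
  overestimates true length by up to ~8% for strokes near 22.5°
  (the staircase metric); straightness inherits the same bias, so the
  straight-fiber checks in the tests use axis-aligned scenes;
* skeleton endpoints retract about half a fiber width from the true
  tips, so traced length underestimates drawn length by roughly the
  fiber width;
* the measured width of oblique strokes is biased low by a fraction of a
  pixel (distance to the nearest background pixel centre, not to the
  continuous boundary);
* on dense crossing scenes, junction resolution is sensitive to raster
  order: a 90° rotation can change the fiber count by a few percent.
  On non-crossing scenes rotation leaves count and cross-links exactly
  invariant (tested).

## The eight features

Per ROI: fea1 is the foreground fraction; fea2 the number of retained
fibers (raw count per tile by default — fibers per mm² is available when
a physical pixel size is known, and the same switch exists for fea6,
since neither normalization is canonical); fea3/fea4 mean fiber
length/width in px; fea5 mean chord-to-path straightness in (0,1];
fea6 cross-links per fiber; fea7 the mean along-fiber geodesic gap
between consecutive cross-links; fea8 the axial order parameter
`R = |Σ p(θ)·e^{2iθ}| / Σ p(θ)` of the angular distribution of FFT
power (Hann-windowed, DC removed, radial band 0.02–0.45 of the side
length), computed on the mask by default so that it measures geometry
rather than intensity texture. `R = 1` for parallel fibers, `R → 0` for
isotropic textures; it is invariant to 90° rotation by construction.

Features undefined for an ROI (no fibers; fewer than two cross-links on
any fiber) are **missing, not zero** — zero-filling would bias patient
means toward "no collagen architecture" readings. Patient-level values
are unweighted arithmetic means over the ROIs where the feature is
defined, missing only if missing in every ROI.

## Feature-score

The published coefficient vector is shipped as a frozen constant and
applied to raw feature values exactly as printed (no standardization is
part of the printed formula). The refit path is ridge-penalized Cox
partial likelihood on z-scored features — survival is the only outcome
analysed, so a Cox response is the coherent choice for refitting even
though the original regression's response is not stated; the published
coefficient magnitudes imply feature scalings that cannot be
reconstructed without the source data, so refit weights are on the
z-score scale and are not comparable to the published ones
coefficient-by-coefficient. The penalty is chosen by k-fold (default 5)
cross-validated partial likelihood over a logarithmic grid
(default 10³…10⁻³); fold assignment is a deterministic function of the
seed. A constant feature is a hard error naming the feature.

## Survival statistics

Cox models use Efron tie handling, Wald confidence intervals, and no
multiple-testing correction (two-sided α = 0.05). Aliased terms and
monotone likelihood raise errors naming the covariate. ROC analysis is
empirical with trapezoidal AUC and DeLong intervals; the cutoff
maximizes the Youden index with ties broken toward higher specificity,
and higher scores mean higher risk. The default ROC outcome is vital
status at end of follow-up (the simplest reading of "predicting OS");
a time-horizon mode (dead by t vs alive at t, censored-before-t
excluded) is available because the target horizon of an OS AUC is
ambiguous. Nomogram points scale each covariate's linear-predictor
contribution so the widest-ranging covariate spans 0–100 points; total
points map to survival through the Efron baseline cumulative hazard at
reference (all-zero) covariates, and a patient at reference levels
recovers the baseline survival exactly (tested as a Cox identity).
Calibration bins patients into quantile bins (default 4) of predicted
survival and compares bin means with the within-bin Kaplan–Meier
estimate at the horizon.

## What the generators emulate — and what they do not

`generate_fiber_image()` draws fibers as smoothed random-walk polylines
(step ≈ 2 px; per-step heading perturbation `N(0, 0.15·waviness)` rad),
with axial orientations from a von Mises distribution on the
half-circle, dilated to the sampled width, on a constant background with
additive Gaussian noise clipped to [0, 4095] and rounded. This spans the
two phenotypes that matter downstream — ordered/abundant/directed versus
sparse/disordered/fragmented — with one parameterization, and gives
exact ground truth (centerlines, widths, orientations, mask, crossing
points). When `crossing_allowed = FALSE`, placement uses rejection
sampling with a guaranteed 3 px gap; dense isotropic non-crossing scenes
may be geometrically unplaceable, which is reported as an error rather
than silently dropping fibers.

It does **not** emulate: optical point-spread blur, intensity falloff
along fibers, multiplicative/Poisson noise, stitching artifacts, or
multi-channel (TPEF) context. Passing tests on these phantoms therefore
demonstrate correctness of the measurement chain, not robustness to
every property of real SHG acquisitions.

`generate_cohort()` draws the eight features as independent Gaussians
and clinical covariates from fixed marginal frequencies typical of a
PDAC cohort (e.g. 80.5% over 50, 63.1% male, 58.4% TNM ≥ IIB), then
event times as exponential with hazard
`h0 · exp(β'·(features − means) + γ'·clinical)` and independent uniform
censoring on [0, T_max], with T_max solved numerically so the expected
censoring fraction matches the request. Real cohorts have correlated
features and non-constant baseline hazards; the exponential choice is
what makes closed-form checks (mean survival, Kaplan–Meier curve,
hazard-ratio recovery) possible.

`simulate_study()` links the two levels: each patient receives a latent
alignment phenotype (log-uniform von Mises κ in [0.25, 32]), the hazard
follows the standardized log-κ (default log-HR 1 per SD), and the
per-patient images are drawn with that κ — so the pipeline must recover
the alignment signal from pixels before any survival association can be
found.

## Problem sizes

The test suite and the staged analysis use sizes chosen so every
stochastic check is comfortably powered while a full run stays
interactive: phantom tiles of 64–384 px with 6–40 fibers and 10-seed
averages for the monotonicity and recovery properties; cohorts of
500–2000 patients for the statistical recovery checks (a balanced binary
covariate at n = 2000 puts the HR = 2 estimate within [1.8, 2.2] for
~95% of seeds); and a 100-patient, one-ROI-per-patient study at 256 px
for the end-to-end alignment-to-survival recovery.

## Known limitations

* Single-channel, 2D, intensity-only: no texture segmentation, no 3D
  reconstruction, no TPEF-derived cellular features.
* Whether the original pipeline joins fibers through junctions, removes
  more than the dimmest mixture component, or normalizes fea2/fea6 per
  area is not reconstructable; all three are exposed as switches with
  the defaults argued above.
* Lengths are reported in pixels unless a physical pixel size is
  supplied.
* The published coefficient set can be evaluated exactly, but the
  original cohort's hazard ratios, AUCs and cutoffs depend on
  undeposited data and are out of reach; the package instead verifies
  each statistical component against simulated ground truth.
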