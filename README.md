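# collascore

Collagen fiber morphometrics and prognostic scoring from
second-harmonic-generation (SHG) microscopy images.

## The problem

The stroma of pancreatic ductal adenocarcinoma (PDAC) is dominated by a
dense collagen matrix, and the architecture of that matrix — how much
collagen there is, how long, wide, straight, aligned and interconnected
the fibers are — carries prognostic information. SHG microscopy images
fibrillar collagen without labels, so collagen architecture can be
quantified directly from grayscale 12-bit SHG tiles.

`collascore` implements the full quantification-to-prognosis pipeline for
researchers working with SHG (or SHG-like) images of fibrous tissue:

1. **Segmentation** — a Gaussian mixture model fitted to the intensity
   histogram by EM separates collagen from background
   (`fit_gmm()`, `segment_collagen()`).
2. **Fiber network extraction** — the binary mask is thinned to a
   unit-width skeleton, decomposed into individual fibers (ordered vertex
   lists) with angle-based joining at junctions, and vertices shared by
   two or more fibers are marked as cross-link points
   (`skeletonize_mask()`, `extract_fiber_network()`,
   `detect_crosslinks()`).
3. **Eight collagen features** per region of interest (ROI), averaged per
   patient (`compute_feature_vector()`, `aggregate_patient()`):

   | feature | meaning |
   |---|---|
   | fea1 | collagen proportionate area (fraction of pixels) |
   | fea2 | fiber number |
   | fea3 | mean fiber length (px) |
   | fea4 | mean fiber width (px) |
   | fea5 | mean fiber straightness (chord / path, in (0,1]) |
   | fea6 | cross-link density (cross-links per fiber) |
   | fea7 | mean cross-link spacing along fibers (px) |
   | fea8 | orientation index (FFT axial order parameter, [0,1]) |

4. **Feature-score** — the linear combination
   `score = Σ wᵢ · feaᵢ` with either the published coefficient set

   ```
   score = -7.7656606·fea1 - 44.6439289·fea2 + 0.309178·fea3
           + 0.8884292·fea4 - 1.1665562·fea5 + 10.1583025·fea6
           - 0.1356464·fea7 + 0.6020531·fea8
   ```

   (`published_score_coefficients()`, `compute_feature_score()`) or
   coefficients refit on a training cohort by cross-validated
   ridge-penalized Cox regression (`fit_ridge_cv()`).
5. **Prognostic evaluation** — univariate/multivariate Cox models with
   Efron ties and Wald intervals, Kaplan–Meier curves with log-rank
   tests, ROC/AUC with DeLong intervals and Youden-index cutoffs,
   nomogram point scales and calibration curves
   (`cox_fit()`, `km_logrank()`, `roc_youden()`, `build_nomogram()`,
   `calibration_curve()`).

Because studies of this kind rarely deposit raw images, the package also
ships first-class generators for SHG-like fibrous phantoms with known
ground truth (`fiber_spec()`, `generate_fiber_image()`) and for simulated
survival cohorts under a proportional-hazards model
(`cohort_spec()`, `generate_cohort()`, `simulate_study()`), which drive
the whole test suite.

## Worked example

```r
library(collascore)

spec <- fiber_spec(n_fibers = 15, size = 256, orientation_mean = 30,
                   orientation_kappa = 12, waviness = 0.2, seed = 7)
g   <- generate_fiber_image(spec)     # 12-bit image + ground truth
res <- analyze_image(g$image, seed = 1)
round(res$features, 3)
#>    fea1    fea2    fea3    fea4    fea5    fea6    fea7    fea8
#>   0.129  14.000 108.297   4.455   0.923   0.357  59.567   0.842
compute_feature_score(res$features)
#> [1] -593.595
```

Read: 12.9% of the tile is collagen; 14 fibers were traced (one pair of
the 15 drawn fibers merged at a shallow crossing), with mean length
108 px, width 4.5 px, straightness 0.92; 0.36 cross-links per fiber with
59.6 px spacing; and a strong alignment index of 0.84 (the fibers were
drawn with a concentrated orientation distribution). The score is the
published linear combination of those eight values — on raw features it
is dominated by the fiber count term; the ridge-refit path standardizes
features first.

The `analysis/` directory holds the staged workflow on a simulated
100-patient study: `01_simulate_study.R` (images + clinical table with an
alignment-linked hazard), `02_image_features.R` (image analysis),
`03_scoring.R` (train/validation split and ridge-Cox refit) and
`04_survival_analysis.R` (Cox, nomogram, calibration, ROC/Youden,
Kaplan–Meier). Each stage prints what it found and writes its tables to
`results/`.

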