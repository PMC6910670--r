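---
title: "Delta-radiomics with machine-learning feature selection: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delta-radiomics with machine-learning feature selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the pipeline

`deltarad` implements a longitudinal ("delta") radiomics analysis for
small imaging cohorts: given co-registered 3D volumes of a tumor at a
pre-treatment and one or more post-treatment time points, in two MRI
modalities (T1 and T2-FLAIR), with one clinician-drawn gross tumor volume
(GTV) mask per patient, it asks whether the *change* in quantitative image
texture inside the GTV predicts a dichotomized survival outcome (class 0:
overall survival < 12 months; class 1: >= 12 months) better than the
single-time-point image does.

The pipeline is:

1. **Quantization.** In-mask intensities are re-binned to G = 64 grey
   levels, equal-width between the ROI minimum and maximum (the maximum is
   assigned to bin G so the top bin is never empty; a constant ROI maps to
   level 1 and is flagged degenerate).
2. **Extraction.** 61 features per (volume, mask): 22 grey-level
   co-occurrence (GLCOM), 11 run-length (GLRLM), 13 size-zone (GLSZM) and
   5 neighbourhood grey-tone difference (NGLDM) texture features, 6
   morphological and 4 intensity-histogram features
   (`feature_registry()` fixes names and order).
3. **Delta features.** For each feature F and post-treatment time point,
   the relative change `dF = (F_post - F_pre) / F_pre`, giving five
   categories: F_pre, F_post1, F_post2, dF1, dF2. T1 and T2-FLAIR
   features are concatenated with modality prefixes (2 x 61 = 122 columns
   before degenerate-column dropping).
4. **Normalization.** Each category is z-scored column-wise over the
   whole dataset (population SD). Whole-dataset scope is the study's
   stated convention for a 12-patient cohort; `train_only` is available
   to quantify the (mild, feature-only) leakage it implies.
5. **Two-step selection, inside every cross-validation fold.** First a
   univariate Cox proportional-hazards screen keeps features whose
   likelihood-ratio test against the null model has p < 0.1 (strict);
   then one of three multivariate rankers picks the top N (N = 1..3):
   random-forest out-of-bag permutation importance, neural-network input
   ablation, or L1-logistic-regression weight magnitude.
6. **Classification.** Seven classifiers (RF with 100 trees, L1-LR,
   L2-LR, linear SVM, Gaussian-RBF SVM, a 3-layer 10-hidden-unit
   back-propagation network, Gaussian naive Bayes), each emitting a
   class-1 posterior-style score in [0, 1].
7. **Evaluation.** Leave-one-out cross-validation; the n held-out scores
   are pooled, thresholded at every distinct score, and the ROC is
   integrated by trapezoid (this equals the tie-corrected Mann-Whitney
   statistic, which the tests assert to 1e-12). Each of the
   3 selectors x 7 classifiers = 21 model combinations is repeated for 50
   iterations; per-category results are compared by paired-sample t-test
   across the 21 combinations, and one AUC per combination is reported as
   the best mean AUC over N (max-over-N convention).

## Texture-matrix conventions

The four texture families need 3D accumulation conventions, fixed here
and switchable where meaningful:

* **GLCOM**: one symmetric matrix summed over the 13 unique distance-1
  directions of the 26-neighbourhood, restricted to in-mask pairs, then
  normalized (summed-matrix aggregation rather than per-direction feature
  averaging; `glcom_features(q, directions = ...)` accepts any direction
  set). Correlation of a single-level ROI is defined as 0.
* **GLRLM**: runs are maximal in-mask collinear same-level sequences,
  matrices summed over the same 13 directions. Run percentage divides by
  (in-mask voxels x number of directions), so a single-direction call on
  a straight line of length L yields RP = 1/L.
* **GLSZM**: zones are 26-connected components of equal level.
* **NGLDM**: Amadasun-King accumulators over in-mask 26-neighbourhoods;
  coarseness and texture strength carry a 1e-12 denominator guard so a
  constant ROI stays finite; contrast and busyness of a single-level ROI
  are 0 by convention.

Every texture feature is verified against a brute-force oracle
(pair/run/zone/neighbourhood enumeration with independently coded
formulas) on random ROIs to 1e-10 relative.

**Morphology** uses the exposed-voxel-face boundary mesh for surface area:
every mask-voxel face adjacent to background contributes its physical
area. This is exact for axis-aligned shapes — the test oracle is the
analytic cuboid — and it is deterministic. It overestimates the area of
smooth shapes (a rasterized ball measures ~1.5x the spherical area), so
sphericity `(36 pi V^2)^(1/3) / A` stays strictly below 1 for every voxel
set; only cross-patient *contrasts* of these features matter in this
pipeline, and with a mask shared across time points all morphological
delta features are exactly 0 (asserted by the acceptance suite). The six
features are volume, surface area, surface-to-volume ratio, sphericity,
compactness `36 pi V^2 / A^3`, and maximum 3D diameter (largest pairwise
distance between boundary-voxel centers).

**Histogram** features are population (n-denominator) moments of the raw,
unquantized in-mask intensities; skewness and excess kurtosis of a
constant ROI are 0 by convention.

## The synthetic cohort generator

No imaging data ships with the package; `generate_cohort()` emulates the
study conditions so every downstream stage is testable:

* 12 patients, 32^3 voxel grids at 1 mm isotropic, one ellipsoidal GTV
  per patient (semi-axes drawn within +/-15% of min(grid)/4.5, about
  700-2000 voxels) shared by all six volumes — tumor geometry varies
  across patients but not across time, exactly as when contours are
  transferred between registered scans.
* Pre-treatment volumes are label-independent textured random fields:
  per-patient, per-modality base intensity (T1 ~ N(100, 10), T2-FLAIR ~
  N(140, 10)) plus Gaussian-smoothed noise (correlation length 2 voxels,
  sd 10 intensity units).
* Post-treatment volumes add smooth scan-to-scan noise (sd 1) everywhere
  and, for class-1 patients only, a voxel-wise white-noise perturbation
  of sd `effect_size` *inside the GTV of the T1 volumes*. This plants a
  post-treatment texture change — it raises the high-frequency texture
  statistics (GLCOM contrast-type, NGLDM, short-run / small-zone
  features) of T1 delta features as a correlated family — while
  pre-treatment features carry no class information by construction.
  `effect_size = 0` disables it; the perturbation field is drawn
  unconditionally so same-seed cohorts differ across effect sizes only in
  the planted voxels (a tested contract).
* Survival: class labels are assigned to `class_balance` of the cohort
  (default 6/12); OS is uniform on [5.3, 12) months for class 0 and
  [12, 29.4] for class 1, matching the study's printed OS range, with an
  optional `censoring_fraction` (default 0 — the study reports no
  censoring).

What the generator does **not** emulate: MRI physics (bias fields, Rician
noise, partial volume), registration error, contour variability, scanner
drift, or biologically structured texture. Passing tests therefore show
that the *pipeline* recovers a planted longitudinal texture signal at
desk scale, not that any particular feature is prognostic in real
gliomas.

Because the perturbation moves a correlated family of texture features,
no single image-level feature can dominate a selection-frequency tally;
the planted-feature recovery tests therefore operate on feature tables
with a single informative column among noise columns, which exercises the
same in-fold Cox + ranking machinery with an unambiguous ground truth.

## Fixed parameters and numerical choices

| Parameter | Default | Why |
|---|---|---|
| Grey levels G | 64 | study convention |
| Cox screen alpha | 0.1 (strict <) | study convention; LRT against the null model (Wald optional) |
| N selected | 1..3, capped per fold at the number of survivors | study convention; a fold with k < N survivors uses k |
| RF | 100 trees; unscaled OOB permutation importance | study convention / cited importance method |
| NN | 10 hidden sigmoid units, full-batch backprop, cross-entropy, 500 epochs, lr 0.01, init U(-0.5, 0.5) | width from the study; budget/rate pinned for reproducibility and verified on separable and planted-signal cases |
| SVMs | cost 1; RBF gamma = 1/n_features; sigmoid-mapped decision value as score | unstated in the study; Platt calibration is impractical inside n = 11 folds and ROC needs only ranking |
| LR classifiers | glmnet lambda = 1/n (unit inverse-regularization) | unstated; pinned |
| L1 selector penalty | lambda 1.0, halved up to 10x if all coefficients vanish | pinned with an explicit fallback |
| z-score | population SD, whole dataset | fixed so tests are exact; matches the study's stated scope |
| Delta guard | baseline magnitude < 1e-9 marks the delta undefined; such columns are dropped and logged | unbounded ratios would dominate z-scores |
| Iteration seeds | derived per (category, selector, classifier, N, iteration, fold) from one base seed | exact replay; cells are independent |

Across the 50 iterations only the stochastic stages vary (RF bootstraps
and permutations, NN initialization); LOOCV folds are exhaustive, so
fully deterministic selector-classifier cells are computed once and
replicated, which changes nothing numerically and keeps the grid fast.

## Known limitations: pooled LOOCV scores are pessimistically biased

Pooling the n held-out scores of leave-one-out cross-validation into one
ROC is the study's evaluation design, and it has a known structural bias
at this sample size: with 6/6 classes, the training set of each fold is
imbalanced 5:6 *against* the held-out patient's class, so every model's
score shifts toward the training majority and the pooled scores anti-rank
the classes. Under label permutation the grid's mean AUC therefore falls
well below 0.5 (the calibration test in the acceptance suite computes the
per-cell means; weakly-trained models are the most affected) instead of
centering on it. The package reproduces this faithfully rather than
correcting it; it also explains how AUCs far below 0.5 can legitimately
appear in screen-only comparisons. The calibration test's *upper* bound —
no cell drifts above 0.6, i.e. no optimistic leakage of the held-out
patient into selection or training — holds, and a dedicated test asserts
that a patient's own survival record never influences their held-out
score. Analyses that need unbiased null calibration at this design point
should prefer per-fold-averaged ROC or corrected resampling schemes,
which are outside this package's scope.

Problem sizes used by the test suite are the study's own (12 patients,
50 iterations or 50 seeds, 21 combinations, N = 1..3); unit tests use
smaller grids (16^3-24^3 voxels, 8 patients) where only mechanics are at
stake.
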