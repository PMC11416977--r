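---
title: "Radiomic modelling of tumor immune infiltration: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radiomic modelling of tumor immune infiltration: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`timeradiomics` implements a two-cohort radiomic study design: CT
texture models of tumor immune microenvironment (TIME) infiltration are
learned on a surgical cohort, transferred to an immunotherapy cohort,
and the predicted infiltration groups are tested against treatment
response and progression-free survival (PFS). This vignette documents
the models, the synthetic data they are exercised on, the numerical
conventions, and the design choices that were genuinely open.

## The synthetic cohorts

No patient data ships with the package; the generator produces the
statistical structure the analysis assumes.

**Phantom images.** Each case is an ellipsoidal tumor ROI inside a CT
grid. Outside the ROI, voxels are independent Gaussian background noise
(default mean −800 HU, SD 30 HU — lung-like attenuation). Inside, the
texture is `roi_mean + texture_contrast × G`, where `G` is smoothed
white noise (Gaussian kernel, width = `texture_correlation_length`,
default 2 mm) rescaled to unit variance by the exact ℓ₂ norm of the
kernel. This is the simplest stationary field with a tunable,
analytically checkable second-order structure: the ROI voxel variance
equals `texture_contrast²` in expectation, which the tests verify
directly. Defaults: 32³ voxels, 1 mm isotropic spacing, semi-axes
10 mm, contrast 40 HU, ROI mean 40 HU (soft tissue). ROI semi-axes
receive a ±20 % per-case size jitter that is independent of the labels.

**Infiltration.** Flow-cytometry-style percentages are sampled
hierarchically: CD3 ~ 100·Beta(5, 3), CD8 = CD3·Beta(4, 4),
TRM = CD8·Beta(3, 3). Nesting enforces TRM ≤ CD8 ≤ CD3 per case by
construction. The distributions themselves are a modelling choice, not
an inference from data — the source domain reports percentages without
marginals — so the defaults aim only for plausible ranges (CD8 centred
near 31 % with SD ≈ 13 %). The latent driver of both imaging and
outcome is the CD8 percentage standardized by its closed-form marginal
moments, so standardization never depends on the realized cohort.

**Image–label coupling.** The ROI texture mean is shifted by
`effect_size × latent_cd8` texture-SDs. `effect_size = 0` therefore
makes images exactly independent of all labels (the null the tests
exploit); `effect_size = 2` produces a ≥ 2 SD mean shift between
infiltration extremes and near-perfect downstream discrimination.

**Outcomes.** Response categories PD < SD < PR < CR follow a
proportional-odds model on latent CD8, with baseline probabilities
(0.089, 0.161, 0.679, 0.071) matching the shape of a typical
checkpoint-inhibitor cohort. PFS is exponential with baseline median
10.3 months and log hazard ratio `survival_link` per latent CD8 unit
(default log 0.218 — strong protection from infiltration). Censoring is
an independent per-case exponential calibrated so that a fraction
`censoring_rate` (default 2 %) of cases is censored, capped at a
24-month administrative horizon; `censoring_rate = 0` disables
censoring entirely so that every event is observed.

**Seeding.** One global seed fans out to per-case substreams
(`child_seed`), so enlarging a cohort never perturbs earlier cases and
every generator is a pure function of its spec.

What the generator does *not* emulate: scanner noise spectra, partial
volume effects, anatomically realistic tumor shapes, correlated
clinical covariates, or inter-scanner batch effects. Passing tests
therefore demonstrate the pipeline's statistical machinery, not
clinical performance on real CT data.

## Feature extraction

The extractor reproduces the conventional 851-feature radiomic surface:
seven families over the original image and the eight sub-bands of a
single-level wavelet filter bank — 18 first-order + 24 GLCM + 16 GLRLM
+ 16 GLSZM + 5 NGTDM + 14 GLDM per image (93 × 9 = 837) plus 14 shape
features on the original mask only.

* **Discretization** is fixed-bin-width (default 25 HU), anchored at
  the ROI minimum: `level = floor((HU − min)/width) + 1`. Fixed bin
  width is the de-facto CT convention and keeps the number of gray
  levels data-adaptive; it also makes every texture family invariant to
  a constant HU shift (verified by test), while first-order
  `Mean`/`Energy` intentionally are not.
* **Wavelets.** The bank is a stationary (undecimated) separable
  single-level transform with symmetric boundary extension; Coiflet-1
  is the default analysis wavelet and sub-bands keep the input grid
  shape. Keys `LLL…HHH` apply per letter to the (z, y, x) axes — the
  convention used by the common radiomics toolchains. The low-pass
  filter carries the orthogonal-wavelet DC gain of √2 per axis.
* **Texture matrices** (co-occurrence, run length, size zone,
  neighbourhood tone difference, dependence) are built in C++ and
  verified voxel-for-voxel against brute-force R enumerations on a fuzz
  suite of small grids. Directional families use the 13 unique
  distance-1 offsets of the 26-neighbourhood and average feature values
  over directions (matrices are not merged). GLCMs are symmetrized and
  normalized per direction; MCC is the square root of the
  second-largest eigenvalue of the transition-normalized matrix, with
  MCC = 1 when only one gray level is present.
* **Degenerate values.** Every 0/0 resolves to a documented constant —
  e.g. a constant ROI has Correlation 1, entropies 0, NGTDM Contrast 0,
  Coarseness capped at 10⁶ — never `NaN`, so downstream matrices are
  always finite; `extract_all()` errors if any feature evaluates
  non-finite.
* **Shape.** Surfaces are triangulated by marching tetrahedra over the
  0.5 level set of the binary mask smoothed with a 1-voxel Gaussian
  ("anti-aliased" meshing, with linear interpolation of crossing
  points). Meshing the raw binary indicator overestimates the area of a
  digitized ball by ~30 % (the staircase artefact); the smoothed mesh
  recovers sphere area within ~1 % and keeps Sphericity ≤ 1 by the
  isoperimetric inequality, since area and volume come from the same
  closed mesh. For masks so small that the smoothed field never crosses
  0.5, the mesher falls back to the binary indicator. Principal-axis
  lengths use the sample covariance of physical voxel centres; a
  single-voxel mask has axis lengths 0 and Elongation = Flatness = 1 by
  convention.
* **Windowing.** The CT display window (level 50 HU, width 2000 HU,
  i.e. clip to [−950, 1050]) belongs to the segmentation context, so
  `apply_window()` is exposed but extraction defaults to raw HU —
  windowing first would silently saturate first-order statistics.
  Extraction crops to the ROI bounding box plus a 4-voxel margin; the
  margin exceeds the wavelet half-length, so voxels beyond it cannot
  influence any feature (tested).

## Robustness, matrices, model exploration

Intra-observer stability uses ICC(2,1) — two-way random effects,
absolute agreement, single measurement — the standard choice for
re-segmentation studies; features with ICC strictly above 0.80 are
retained. The second rater is emulated by randomly dilating/eroding the
mask boundary. A zero-variance rating table returns ICC 1 (identical
constants agree perfectly).

Labelled matrices encode: infiltration dichotomized at the cohort
median (ties to the low group), response CR/PR → 1 vs SD/PD → 0, and
12-month progression (event at ≤ 12 months → 1; follow-up beyond 12
months → 0; censored before 12 months → excluded as indeterminate).
Z-score normalization uses the population (1/n) SD and is fitted on
training rows only; applying a fitted transform to an already
normalized matrix is refused via a state flag, because the transform is
not idempotent. Correlation screening drops the *later* feature (in
manifest order) of any pair with |Pearson r| > 0.99 — absolute value,
so a feature and its negation also count as duplicates — making the
retained set deterministic given the column order.

The exploration engine evaluates every (selector, classifier, k)
configuration on a single stratified 70/30 split: ANOVA (F statistic),
Kruskal–Wallis (tie-corrected H), RFE (recursive elimination under an
L2 logistic base model, eliminating ~10 % of remaining features per
refit until few remain), and Relief (k = 3 nearest hits/misses, all
cases as anchors); nine classifiers (the grid omits the vendor's
auto-encoder entry, which has no reproducible definition); k ∈ 1…10.
Ranking is by independent-test AUC with ties resolved to fewer
features, then canonical selector/classifier order. The whole run is a
pure function of `(matrix, grid, seed)`, and permuting test labels
cannot change any fitted model (tested).

The integrated TIME–immunotherapy model refits the TIME-winning
classifier on the full surgical cohort over the *union* of the TIME and
response retained feature sets, applies surgical-cohort normalization
parameters unchanged to the immunotherapy rows, and dichotomizes
predicted infiltration at the Youden-optimal threshold fitted on the
surgical cohort. Union/refit/Youden is one concrete reading of a
one-sentence description in the source design; intersection and
TIME-features-only variants are exposed via `combine=`.

## Clinical statistics

AUC is the Mann–Whitney concordance with half credit for ties, its
variance and the paired AUC comparison follow DeLong's placement-value
construction (cross-checked against pROC), and both are verified
calibrated: type-I error within the binomial 95 % band of α = 0.05 over
hundreds of null replicates. "Mean progress time ± x" is computed as
the restricted mean survival — the area under the Kaplan–Meier curve up
to the largest observed time — with the standard KM-mean variance. The
Breslow test is the generalized Wilcoxon with weight equal to the
number at risk, computed directly from the per-event risk tables (the
`survdiff` rho family uses Peto–Peto weights instead); the tests
verify its null behaviour and that it out-ranks the log-rank test
exactly when group differences are concentrated early. Cox models maximize the
Breslow-ties partial likelihood (via the survival package) and are
verified against one-dimensional grid maximization; contingency tables
use Pearson chi-square without continuity correction, falling back to
Fisher's exact test when any expected cell is below 5 — the printed
percentages, not the p-values, are the reproducible quantity in the
source tables. Disease control is defined as CR/PR/SD in the pipeline
report.

## Problem sizes and determinism

The test suite and the acceptance script run the full study at reduced
sizes chosen to exercise every stage meaningfully: 16³–32³ phantoms,
cohorts of 16–120 cases for end-to-end checks, 400 cases for
hazard-ratio recovery, and 400–500 replicates for calibration. These
sizes are the package's own trade-off between Monte-Carlo error and
run time; the full-study shape (135/112 cases, the 360-point grid) is
available through `run_config()`. Reports serialize to JSON with full
precision, and re-running `run_study()` under an identical config
yields byte-identical output.

## Known limitations

* The phantom is statistically, not anatomically, realistic; absolute
  feature values should not be compared against patient data.
* The single-split exploration protocol mirrors the emulated design but
  is optimistic relative to nested cross-validation; the package
  deliberately does not add tuning the design lacked.
* GLSZM/GLDM use 26-connectivity and distance-1 neighbourhoods only;
  Laplacian-of-Gaussian and 2D extraction modes are out of scope.
* ICC confidence intervals and inter-scanner robustness designs are not
  implemented.
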