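# timeradiomics

Non-invasive assessment of the tumor immune microenvironment (TIME) is a
central problem in immuno-oncology: checkpoint-inhibitor response in
non-small-cell lung cancer tracks the density of tumor-infiltrating
CD3+ T cells, cytotoxic CD8+ T cells and tissue-resident memory
(CD8+ TRM) cells, but those densities are normally measured by flow
cytometry on resected tissue, which advanced-stage patients cannot
provide. `timeradiomics` implements, as a fully tested desk-scale R
pipeline, the radiomic alternative: learn CT texture signatures of
infiltration on a surgical cohort, transfer the predicted infiltration
level to an immunotherapy cohort, and ask whether the predicted TIME
stratifies treatment response and progression-free survival (PFS).

The package is aimed at methodologists who want an end-to-end,
reproducible reference implementation of this class of study — every
stage runs on synthetic phantom data generated by the package itself, so
no patient data or downloads are required.

## What is implemented

* **Phantom/cohort simulator** — ellipsoidal tumor ROIs carrying a
  correlated Gaussian random-field texture in HU, with per-case
  infiltration percentages (nested Beta marginals enforcing
  TRM ≤ CD8 ≤ CD3), an ordinal CR/PR/SD/PD response linked to latent CD8
  by a proportional-odds model, and exponential PFS with log hazard
  ratio `survival_link` per latent CD8 unit. Everything is a pure
  function of its seed.
* **Radiomic features** — the standard 851-feature surface: 18
  first-order + 24 GLCM + 16 GLRLM + 16 GLSZM + 5 NGTDM + 14 GLDM
  features on the original image and the eight sub-bands of a
  single-level undecimated coif1 wavelet transform, plus 14 shape
  features from a triangulated mask surface
  (162/14/216/144/144/45/126 = 851). Texture matrices are built in C++
  and verified against brute-force enumeration.
* **Robustness filter** — ICC(2,1) between two raters' extractions;
  features with ICC > 0.80 are retained.
* **Model exploration** — stratified 70/30 split, Z-score normalization
  and |PCC| > 0.99 deduplication fitted on training rows only, then a
  grid over 4 selectors (ANOVA, Kruskal–Wallis, RFE, Relief) × 9
  classifiers (SVM, LDA, RF, LR, LR-LASSO, AdaBoost, DT, GP, NB) × 1–10
  features, ranked by independent-test AUC
  (`AUC = P(score⁺ > score⁻) + ½P(tie)`).
* **Clinical statistics** — ROC with DeLong variance and the paired
  DeLong test, Youden-optimal cutoffs, disease-control-rate tables with
  chi-square/Fisher, Kaplan–Meier fits with restricted-mean survival,
  log-rank and Breslow (Gehan–Wilcoxon, weight = number at risk) tests,
  and multivariable Cox models (Breslow ties) with risk-score AUC.

## Worked example

```r
library(timeradiomics)

cfg <- run_config(seed = 1, n_time = 30, n_ici = 30, effect_size = 2,
                  phantom = phantom_spec(grid_shape = c(16, 16, 16),
                                         roi_axes = c(5, 5, 5)),
                  grid = model_grid(selectors = "ANOVA",
                                    classifiers = c("LR", "NB"),
                                    n_features = c(2, 4)),
                  n_rater_cases = 8)
report <- run_study(cfg, verbose = TRUE)

report$robustness
#> $n_features
#> [1] 851
#> $n_retained
#> [1] 246

vapply(report$time_models, `[[`, 0, "test_auc")
#>   cd3   cd8   trm
#> 0.775 0.800 0.700

report$integrated$cd8$response_auc
#> [1] 0.8708134
```

At this demo scale 851 features are extracted per case and 246 survive
the intra-observer ICC filter. The three TIME models discriminate high
vs low infiltration on their held-out cases (test AUCs 0.70–0.80), and
transferring the CD8 model to the immunotherapy cohort predicts the
CR/PR vs SD/PD response with AUC 0.87 — the simulated
texture–infiltration–outcome coupling is strong by default. At 30 cases
per cohort the multivariable Cox fit in `report$cox` is often
degenerate (predicted groups can separate the few progression events
perfectly); larger, slower configurations (`n_time = 135`,
`n_ici = 112`, `grid = model_grid()`) reproduce the full study shape.

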