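# radrep

Joint analysis of the **reproducibility** and **prognostic value** of
radiomic texture features under varying CT reconstruction, for people
building quantitative-imaging biomarkers (radiomics researchers, imaging
statisticians). When the same scan is reconstructed at different slice
thicknesses (2.5 / 3.75 / 5 mm) and iterative-denoising (ASiR) levels,
texture features drift; a feature is only a usable biomarker if it is both
stable under that drift *and* related to outcome. `radrep` implements the
whole workflow on synthetic data: phantom and cohort generators, a
93-feature extractor, concordance-based reproducibility analysis, survival
discrimination, and reproducibility-aware model selection.

## What it computes

**Reproducibility.** For paired reconstructions, Lin's concordance
correlation coefficient

> CCC(x, y) = 2 cov(x, y) / (var(x) + var(y) + (mean x − mean y)²)

is computed per feature across slice-thickness pairs at a fixed ASiR level,
with paired Wilcoxon signed-rank comparisons between pairs. Across the full
3 × 7 reconstruction grid, a linear mixed model
`value ~ thickness + ASiR + (1 | subject)` (REML) decomposes each feature's
variance into subject (σ²ₛ), thickness (σ²ₜ), ASiR (σ²ₐ) and residual (σ²ₑ)
components, giving the **generalized CCC**

> CCC = σ²ₛ / (σ²ₛ + σ²ₜ + σ²ₑ)

with σ²ₐ excluded because ASiR is controlled for as a fixed effect.

**Prognosis.** Per-feature discrimination of right-censored survival by
Harrell's C-index (features oriented so C ≥ 0.5), and a multivariable
experiment: candidate features thresholded on generalized CCC, filtered on
oriented C ≥ 0.55 and univariate Cox p < 0.1, reduced by mRMR, and fitted in
a Cox proportional-hazards model — all inside event-stratified, repeated
10-fold cross-validation, over a 9 feature-set × 5 CCC-threshold × 7
feature-count grid (315 cells).

**Joint view.** Pareto fronts over (CCC, C-index), best-extractor tallies
per feature and ROI, and Ward-linkage clustering data for heat maps.

**Extraction.** 93 features (18 first-order + GLCM 24, GLRLM 16, GLSZM 16,
GLDM 14, NGTDM 5) from NIfTI image/mask pairs after cubic-spline
resampling, HU-window resegmentation ([−50, 350]) and 24-bin
discretization, under eight extractor settings (`L2i, L2, L3, S2i, S2, S3,
A2, A3`) crossing resampling targets with 2.5D/3D texture aggregation.

## Worked example

Simulate two features over the reconstruction grid for 120 subjects — one
engineered to be thickness-sensitive (σ²ₜ = 1), one stable (σ²ₜ = 0.05) —
then measure their reproducibility:

```r
library(radrep)

ft <- generate_feature_table(120, list(
  glcm_Contrast   = effect_spec(sigma_s2 = 4, sigma_t2 = 1,    sigma_a2 = 2,   sigma_e2 = 0.5),
  firstorder_Mean = effect_spec(sigma_s2 = 4, sigma_t2 = 0.05, sigma_a2 = 0.2, sigma_e2 = 0.1)),
  seed = 7)

pairwise_ccc_table(ft)[, c("feature", "comparison", "ccc")]
#>           feature  comparison   ccc
#> 1 firstorder_Mean 2.5_vs_3.75 0.963
#> 2 firstorder_Mean    2.5_vs_5 0.949
#> 3 firstorder_Mean   3.75_vs_5 0.969
#> 4   glcm_Contrast 2.5_vs_3.75 0.792
#> 5   glcm_Contrast    2.5_vs_5 0.578
#> 6   glcm_Contrast   3.75_vs_5 0.771

generalized_ccc_table(ft)[, c("feature", "ccc", "sigma_s2", "sigma_t2", "sigma_e2")]
#>           feature   ccc sigma_s2 sigma_t2 sigma_e2
#> 1 firstorder_Mean 0.960     3.57   0.0473    0.102
#> 2   glcm_Contrast 0.708     3.57   0.9770    0.497
```

Read: the thickness-sensitive feature loses the most concordance on the
widest gap (2.5 vs 5 mm, CCC 0.578) and its generalized CCC (0.708) is close
to the analytic value σ²ₛ/(σ²ₛ+σ²ₜ+σ²ₑ) = 4/5.5 ≈ 0.727, while the stable
feature stays near 0.96. The fitted components recover the generating ones.

From there, `generate_survival_cohort()` + `repeated_cv()` evaluate any
(feature set, CCC threshold, feature count) cell, `experiment_grid()` runs
the full 315-cell design, and `per_feature_extractor_analysis()` /
`cluster_heatmap_data()` produce the joint reproducibility-vs-prognosis
summaries. `run_pipeline(pipeline_config(outdir))` drives the whole chain —
phantom simulation, 21-reconstruction extraction, CCC tables, synthetic
survival cohort, CV grid, reports — and writes CSV/JSON artifacts plus a
manifest with config hash and checksums.

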