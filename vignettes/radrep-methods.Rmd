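---
title: "Methods: joint reproducibility and prognosis analysis of radiomic features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: joint reproducibility and prognosis analysis of radiomic features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(radrep)
```

## The problem

Radiomic signatures — predictive models built from quantitative features of
medical images — are only clinically useful if their inputs are stable under
the image-acquisition variation seen in practice. For CT of the liver, the
slice thickness chosen at reconstruction time is a major source of such
variation: the same raw scan reconstructed at 2.5, 3.75 or 5 mm yields
systematically different texture feature values. `radrep` implements a
complete workflow for studying this problem jointly with prognostic value:

1. emulate a *reproducibility arm*, in which each subject's volume exists in
   every cell of a 3 slice-thickness x 7 denoising-level (ASiR-like)
   reconstruction grid;
2. extract a standard 93-feature set from two regions of interest (an
   ellipsoidal "tumor" and a surrounding "parenchyma" shell) under eight
   resampling/aggregation settings;
3. quantify per-feature reproducibility by pairwise and mixed-model
   generalized concordance correlation coefficients (CCC);
4. quantify per-feature prognostic value on an independent right-censored
   *survival arm* by Harrell's C-index, and evaluate
   reproducibility-thresholded feature selection inside repeatedly
   cross-validated Cox models;
5. relate the two views through Pareto-efficiency and clustering summaries.

Everything runs on synthetic data generated by the package itself, so the
full analysis is testable end to end without access to patient images.

## Synthetic study arms

### Phantoms and reconstruction variants

`generate_phantom()` builds a stationary correlated Gaussian texture field
(separable Gaussian smoothing of white noise, rescaled to a marginal SD in
HU) on a thin-spacing grid, with an ellipsoidal tumor offset in mean HU from
a surrounding parenchyma shell. Defaults: 20 HU texture SD, 2.5 mm
correlation length, -40 HU tumor contrast over a 100 HU background —
plausible magnitudes for portal-venous liver CT, chosen once as generator
conditions rather than calibrated to any particular scanner. Real CT noise
texture, beam physics and lesion-shape irregularity are *not* modelled;
passing tests therefore demonstrate correctness of the analysis machinery,
not claims about real scanners.

`reconstruct()` emulates a reconstruction variant: thicker slices are
averages of contiguous, non-overlapping blocks of thin slices, and
reconstruction noise is additive zero-mean Gaussian noise whose SD shrinks
linearly with the ASiR-like level (multiplier `1 - 0.5 * asir/60`) and with
the square root of the averaging factor. This reproduces the qualitative
roles of slice thickness and iterative denoising only. Reference masks
follow reconstructions by nearest-neighbor relabelling along z
(`resample_reference_mask()`), mirroring how a reference segmentation is
propagated to other reconstructions in practice.

A note on an invariant: block averaging conserves mean HU exactly over any
region that covers the same physical extent on both grids (the whole
volume, or a box spanning full z). For an ellipsoidal mask the
nearest-neighbor slice resample covers a slightly different region, which
can shift the ROI mean by ~1 HU even for noise-free volumes; this is a mask
effect, not an averaging defect, and the tests distinguish the two.

### Feature tables and survival cohorts

`generate_feature_table()` draws long-format tables with the additive
structure the downstream mixed model assumes:
`value = mean + subject + thickness shift + ASiR shift + noise`, with
independent `subject ~ N(0, sigma_s2)` and `noise ~ N(0, sigma_e2)`. The
fixed level shifts are *monotone*: thickness levels get `(-d, 0, d)` with
`d = sqrt(sigma_t2)`, ASiR levels a linear ramp, both scaled so the
*sample variance* (k-1 denominator) over levels equals the specified
component. That convention matches the estimator (below) exactly, and
monotone shifts make the widest thickness gap the least concordant pair by
construction — the qualitative pattern the pairwise analysis looks for.

`generate_survival_cohort()` draws exponential event times with rate
`baseline_rate * exp(sum(beta * x))` and uniform administrative censoring on
`(0, censor_window)`. Defaults (0.02/month baseline, 120-month window)
give a median survival of roughly three years and a realistic censoring
fraction for a hepatic-resection cohort. Uniform censoring is the simplest
mechanism with a controllable censoring fraction; informative censoring is
out of scope.

## Feature extraction

The preprocessing chain per (image, ROI, setting) is resample, then
resegment, then discretize — the order used by the standard open-source
extractor this feature set follows.

* **Resampling.** Images are interpolated with separable natural cubic
  splines (exact on linear ramps, clamped at the support edge); masks by
  nearest neighbor on the same grid. The output grid covers the input
  bounding box with voxel centres at `origin + (i - 1) * spacing` and the
  first centre shifted by half the spacing difference. The spline order
  (cubic) and edge policy are package choices; they are configurable points
  where conventions differ between toolkits.
* **Resegmentation.** Voxels outside a closed HU window (default
  `[-50, 350]`) are removed, the usual guard against metal artifacts and
  implausible densities.
* **Discretization.** Fixed bin *count* (default 24) over the `[min, max]`
  of retained intensities; the maximum maps to the top bin; a constant ROI
  maps to level 1. Empty bins keep their index — levels are never
  re-compacted, which keeps level distances meaningful across ROIs.

The 93 features comprise 18 first-order statistics (entropy and uniformity
on the discretized levels, everything else on raw HU; percentiles use
linear interpolation) and five texture classes on gray-level matrices:
GLCM (24), GLRLM (16), GLSZM (16), GLDM (14), NGTDM (5). Formulas follow
the common default definitions of the standard extractor; each is
implemented against its matrix definition and checked against brute-force
enumeration oracles in the tests. Conventions worth stating:

* GLDM dependence is `1 +` the number of Chebyshev-distance-1 neighbors
  with an identical level (the center voxel is counted), so the dependence
  index is never zero.
* Undefined values (GLCM correlation on a constant ROI, any directional
  feature on an ROI with no valid voxel pairs) are reported as `NA`, never
  as silent zeros.
* Aggregation: directional classes (GLCM, GLRLM) use one matrix per
  direction — 4 in-plane directions with slice pooling in 2.5D, 13 unique
  3D directions in 3D — with features averaged over directions.
  Non-directional classes (GLSZM, GLDM, NGTDM) use a single matrix with
  8-connected in-plane neighborhoods in 2.5D or 26-connected neighborhoods
  in 3D. For a single-slice ROI the 2.5D matrices coincide with the 2D
  slice matrices.

The eight extractor settings (`extractor_settings()`) cross three
resampling targets (1 mm isotropic, 0.85 mm isotropic, anisotropic
0.85 x 0.85 x 2.5 mm) with 2.5D/3D aggregation, plus two in-plane-only
settings (`L2i`, `S2i`) that preserve native z spacing and therefore only
make sense with 2.5D aggregation. First-order features do not depend on
aggregation, so settings sharing a resampling grid (`S2`/`S3`, `L2`/`L3`)
produce identical first-order values — a structural invariant the tests
assert.

## Reproducibility analysis

**Pairwise phase.** At the reference ASiR level (20%), Lin's CCC —
`2 cov(x, y) / (var(x) + var(y) + (mean(x) - mean(y))^2)` with population
moments — is computed per feature between each pair of slice thicknesses,
and distributions are compared with a paired Wilcoxon signed-rank test.
The test drops zero differences, is fully exact (all `2^n` sign
assignments) for n <= 14, uses the exact signed-rank distribution up to
n = 25 without ties, and otherwise a normal approximation with continuity
and tie corrections.

**Mixed-model phase.** Per feature, `value ~ thickness + ASiR +
(1 | subject)` is fitted by REML over the full 3 x 7 grid. The generalized
CCC is `sigma_s2 / (sigma_s2 + sigma_t2 + sigma_e2)`: the ASiR component is
estimated but *excluded* from the denominator, because ASiR is controlled
for as a fixed effect and its dispersion should not count against agreement
across thicknesses. The thickness (and ASiR) variance is the dispersion of
the estimated fixed-effect levels in the pairwise-difference form
`sum_{i<j} (b_i - b_j)^2 / (k (k - 1))`, which equals the sample variance of
the level effects. This fixed-effect-to-variance conversion is the main
interpretive choice in the model; it is the standard form in the
variance-components CCC literature, and the synthetic generator uses the
same convention so that recovery is exact in expectation. Negative
component estimates are truncated at zero. Noise-free (degenerate) data are
detected by an exact additive-fit check and handled by balanced-design
moment estimates, since REML is unstable at zero residual variance; the
same moment path serves as the fallback if the mixed model fails to fit.

## Survival analysis

Harrell's C-index is computed over comparable pairs (`time_i < time_j` with
subject i an event), crediting score ties 0.5. Features with raw C below
0.5 are negated ("oriented") so all univariate C values lie in [0.5, 1];
orientation is always decided on training data and applied as a sign to
held-out data.

The multivariable experiment crosses 9 feature sets (each extractor setting
alone, plus all pooled), 5 CCC thresholds (0, 0.8, 0.85, 0.9, 0.95) and 7
feature counts (1–64) — 315 cells. Each cell runs repeated, event-stratified
10-fold cross-validation. Within each training fold only:
standardization, orientation, then three ordered filters — generalized CCC
at or above the threshold (the CCC table comes from the separate
reproducibility arm, so applying it globally is leak-free), oriented
C >= 0.55, univariate Cox Wald p < 0.1 — then greedy mRMR selection
(relevance = oriented C - 0.5, redundancy = mean absolute Pearson
correlation, difference form) down to the requested feature count, and a
multivariable Cox fit (partial likelihood, Breslow ties; a light ridge
penalty, theta = 1e-4, is the flagged fallback for singular designs). The
test fold is scored with the training fold's scaling, orientation and
coefficients. A repetition's value is the mean test C over its folds; the
cell summary is the mean over repetitions with a 2.5/97.5 percentile
interval. Folds with no surviving candidate are skipped and counted, so
over-strict thresholds report empty cells rather than failing. Because the
study design never deploys a single final model, no refit on the full
cohort is produced.

Design choices that were genuinely open, and the defaults taken: all
outcome-dependent steps (orientation, filters, selection, fitting) are
refit inside every training fold to avoid optimism; repetition summaries
use percentile intervals across repetitions; folds are stratified by the
event indicator to stabilize the partial likelihood; features undefined for
some subjects are dropped from candidacy rather than imputed; mRMR uses the
difference (not quotient) criterion with C-index-based relevance, since the
outcome is censored.

## Joint reporting

`pareto_front()` returns the subset of (CCC, C-index) points not dominated
by any other point (ties on both coordinates are all retained).
`per_feature_extractor_analysis()` tallies, per feature and ROI, which
extractors attain the highest CCC, the highest C-index, and which are
Pareto-efficient — ties are counted for every tied extractor (full, not
fractional, counting) — and computes the global front over all
(feature, extractor) points, flagging duplicated coordinate pairs (features
that are mathematically equal across settings) with a duplicate-group
column. `cluster_heatmap_data()` supplies Ward-linkage (on Euclidean
distances) row/column orderings and merge trees for CCC and C-index heat
maps; rows are not standardized by default since both quantities already
live on a common scale.

## Problem sizes and numerical choices

The bundled tests and the acceptance script exercise the pipeline at sizes
chosen to make the statistics informative while keeping a full run on a
single CPU in minutes: variance-component recovery at 500 subjects
(tolerance +/- 0.05 on the generalized CCC), the thickness-gap ordering on
200 features x 81 subjects (the size of a realistic prospective
reproducibility cohort), and pipeline recovery on a 400-subject cohort with
5 planted prognostic features (true generalized CCC 0.90, log-hazard 0.5
each) among 200 noise features (true CCC 0.3–0.8) whose reproducibility
table is estimated from 100 subjects. At that size the generalized-CCC
estimator has a standard error of roughly 0.015, so the planted features
clear the 0.85 threshold, and nothing reaches 0.95, by several standard
errors. Phantom-based extraction demonstrations use 24^3-scale grids so a
full 21-reconstruction, 8-setting extraction stays fast.

Other numerical conventions: RNG use is always wrapped so generators are
pure functions of their seed; the pipeline driver fans one global seed out
to per-stage seeds. Cox fits iterate to a 1e-9 relative tolerance with at
most 50 Newton steps. Percentiles use R's default (type 7) linear
interpolation.

## Known limitations

* The phantom texture is a smoothed Gaussian field; real CT noise is
  neither Gaussian nor stationary across the field of view, and ASiR
  changes the noise *texture*, not just its magnitude.
* Slice-thickness emulation by block averaging ignores the reconstruction
  kernel's through-plane response.
* The generalized CCC's fixed-effect dispersion term is an interpretive
  choice (documented above); alternative conventions rescale sigma_t2 by a
  constant factor.
* Shape features, derived-image (wavelet/LoG) features, DICOM ingestion and
  deep-learning segmentation are out of scope by design.
* The cross-validation estimates compare modelling strategies; they are not
  deployment-ready performance claims for any real cohort.
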