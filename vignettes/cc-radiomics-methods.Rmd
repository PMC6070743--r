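---
title: "Corpus-callosum radiomics: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Corpus-callosum radiomics: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccradiomics)
```

## What the package computes

`ccradiomics` implements a complete radiomics workflow for a sagittally
delineated corpus-callosum (CC) region of interest in 3D T1-weighted MR
volumes: per-subject extraction of a fixed 385-feature catalogue, a
three-stage feature-selection cascade, an unpenalised logistic diagnostic
model, and a full ROC / confusion-matrix evaluation. Because clinical MR
images for this problem are typically not shareable, the package also ships
a synthetic-cohort generator that emulates the essential geometry (an
arch-shaped ROI spanning nine sagittal slices) and a controllable
texture contrast between two diagnostic classes, so the entire pipeline is
exercised and validated in code.

## The region of interest and its discretisation

A subject is a 3D scalar volume plus a co-registered binary mask on the same
voxel grid. The sagittal (left–right) axis is identified from the NIfTI
xform (the grid axis with the dominant x component); the ROI *slab* is the
set of `n_slices = 9` contiguous sagittal sections centred on the slice with
the largest mask area. "Central section" is not otherwise well defined for
an arbitrary mask, and the maximal-area rule is reproducible and
anatomy-agnostic; ties break to the lower index. Slabs that would cross the
volume boundary are clipped with a warning.

Texture operators need discrete gray levels. The quantizer pools all in-ROI
intensities across the slab and bins them into `n_levels = 16` equal-width
levels spanning the pooled range, with the maximum intensity closing the top
bin. Sixteen levels is a deliberate compromise: CC ROIs contain a few
hundred pixels per slice, and at much higher level counts the co-occurrence
and run-length matrices become too sparse to be stable. Out-of-ROI pixels
carry the reserved sentinel level 0, which every texture operator skips; a
constant ROI collapses to level 1 and is flagged degenerate.

## The 385-feature catalogue

The catalogue is fixed and ordered, so every subject yields an identically
named vector:

* **42 histogram features** on the raw (unquantized) pooled ROI
  intensities: 21 summary statistics (Min, Max, Range, Sum, Mean, Median,
  Mode, StdDev, Variance, CoefficientOfVariation, Skewness, Kurtosis,
  Energy, Entropy, Uniformity, RootMeanSquare, MeanAbsoluteDeviation,
  MedianAbsoluteDeviation, InterquartileRange, TrimmedMean10, VoxelCount)
  plus the 21 percentiles P1, P5, P10, …, P95, P99.
* **9 formfactor features** of the 3D mask: Volume, SurfaceArea,
  SurfaceVolumeRatio, Sphericity, Compactness1, Compactness2,
  SphericalDisproportion, Maximum3DDiameter, Elongation.
* **144 co-occurrence (GLCM) features**: 8 base statistics (Energy,
  Entropy, Inertia, Correlation, InverseDifferenceMoment, ClusterShade,
  ClusterProminence, HaralickCorrelation) × 6 variants (the four in-plane
  angles 0°/45°/90°/135°, their mean `AllDirection`, and the population SD
  across the four angles `_SD`) × 3 offsets (1, 4, 7 pixels).
* **10 secondary Haralick features** on the angle-averaged offset-1
  matrix: SumAverage, SumVariance, SumEntropy, DifferenceVariance,
  DifferenceEntropy, the two information measures of correlation,
  MaximumProbability, Autocorrelation, Dissimilarity.
* **180 run-length (RLM) features**: 10 base statistics (short/long-run
  emphasis, gray-level and run-length non-uniformity, and the four
  low/high-gray × short/long-run combinations) × the same 6 variants × 3
  run steps.

42 + 9 + 144 + 10 + 180 = 385. Commercial texture packages rarely document
their exact catalogue; this composition is the unique one we found
consistent with both the published total and the naming pattern of the
published signature features (per-angle names such as
`ShortRunEmphasis_angle45_offset1` alongside `_AllDirection_…_SD`
aggregates), and it is frozen as this package's contract.

### Texture conventions

Co-occurrences are counted in 2D within each sagittal slice — the angle set
is planar, matching sagittal delineation — with counts pooled over the nine
slices, symmetrised, and then normalised; features are computed per angle
and aggregated afterwards (mean and population SD over the four angles,
consistent with the `_SD` naming). Diagonal offsets displace by d pixels in
both axes (chessboard metric). For run-length matrices the displacement
parameter is the *run step*: pixels exactly d apart along the scan direction
with the same level continue a run, so d = 1 is the classic RLM and each
scan line splits into d independent lanes for d > 1; out-of-ROI pixels break
runs. The run-length feature with the published rendering "i2j2" is
implemented as i²/j², the standard short-run/high-gray definition, and
ClusterShade's double-centred form uses the symmetric marginal mean
(Σ (i + j − 2μ)³ p). All texture entropies use the natural logarithm;
HaralickCorrelation follows the ITK convention of normalising by the moments
of the marginal-probability vector. Degenerate inputs are mapped to fixed
conventions (zero-variance: Skewness = Kurtosis = Correlation =
HaralickCorrelation = 0; pair-free matrices: all features 0 and the vector
flagged), so feature vectors are always finite.

SurfaceArea counts exposed voxel faces weighted by their physical area.
Face counting systematically overestimates a smooth surface (for a sphere it
converges to 1.5× the true area), which biases Sphericity down to about
2/3 for a ball; the tests assert exactly this face-count behaviour rather
than the smooth-surface ideal, since the definition, not the estimator of a
limit, is the contract.

## Cohort statistics from summary data

Group comparisons reproducible from published "mean ± SD" rows are provided
in closed form: the pooled-variance and Welch two-sample t statistics (in
the control-minus-case sign convention) and the uncorrected Pearson χ² for a
2×2 sex table. Published tables of this kind typically mix the two t
variants without saying so; the package's `variance_gate` reconstructs the
common SPSS behaviour — a two-sided F test on the variance ratio at
α = 0.05 routes to Welch when significant — and this gate reproduces the
pooled/pooled/Welch pattern of the motivating cohort's age, education and
MMSE rows. The χ² is uncorrected because the Yates-corrected value (≈1.66
for the motivating table) is incompatible with the published 2.17.

## The selection cascade

1. **Split first, then preprocess.** The split is stratified by class with
   a seeded uniform shuffle and a floor rule on the training count
   (fraction 0.7); with 78/44 subjects this gives the 54 + 30 / 24 + 14
   composition implied by published test-set denominators. All subsequent
   statistics are anchored on the training partition. Abnormal values —
   non-finite entries and values farther than 3 × IQR from the column
   median — are replaced by the mean of the remaining training values;
   test rows are imputed with the *training* medians/IQRs/means. The same
   anchoring applies to z-scoring (train means and n−1 SDs). We
   deliberately run imputation after the split: imputing on the pooled
   table would leak test-row statistics into training, and leakage-freedom
   is verified in the tests by mutating test rows and asserting an
   identical selection.
2. **Univariate filter.** Per feature, Shapiro–Wilk normality in each
   class at the 0.05 level routes to either a two-sample t test (pooled or
   Welch via the variance gate) or the Mann–Whitney rank-sum test (normal
   approximation with tie correction); features with p < 0.05 survive.
   Reading the "t test and rank-sum together" instruction as a
   normality-routed union is standard radiomics practice; constant
   features get p = 1. The filter's type-I error is calibrated by
   simulation (200 null features, within binomial 99% bounds of 0.05).
3. **Spearman redundancy filter.** Survivors are ordered by ascending
   univariate p (ties to catalogue order) and greedily retained iff their
   absolute Spearman ρ with every retained feature is ≤ 0.9, so of any
   collinear pair the more discriminative member survives. The tie-break
   is our choice; the threshold is the published one.
4. **LASSO.** L1-penalised logistic regression (binomial deviance) over a
   log-spaced 100-point grid spanning four decades below the smallest
   all-zero penalty, with stratified seeded 10-fold cross-validation;
   λ minimising the mean CV deviance is chosen and nonzero-coefficient
   features survive. The published description says "LASSO Cox", but the
   outcome is binary with no survival times, so the binomial family is the
   faithful model. At desk scales the CV-minimum rule recovers planted
   support reliably (all 5 planted features in 20/20 seeds in our checks)
   but is not parsimonious — typically ~15 of 50 candidates survive with
   5 planted — which is the known behaviour of deviance-minimising LASSO;
   we do not assert parsimony.

## The diagnostic model and its evaluation

The final model is unpenalised maximum-likelihood logistic regression on
the selected standardized features; the per-subject *radiomics score* is
its linear predictor, and the sigmoid maps it to a case probability.
Complete or quasi-complete separation — common at desk scales — is detected
from the fitter's fitted-probability warning and handled by a lightly
ridge-penalised fallback (λ = 1e-4) with an explicit `separation` flag, so
scores stay finite and the flag is visible downstream. Classification uses
probability ≥ 0.5 (ties count as positive); AUC uses the Mann–Whitney
identity with ½ credit for ties, which the tests verify equals the
trapezoidal area of the constructed ROC to 1e-12 and matches an independent
ROC implementation. The metric panel (sensitivity, specificity, accuracy,
precision/PPV, NPV) is reported both exactly and rounded half-up to three
decimals; zero-denominator metrics are flagged NA rather than silently 0.
On a 24-positive/14-negative test partition an exhaustive search shows
exactly one confusion matrix — TP = 19, FN = 5, TN = 7, FP = 7 —
reproduces the panel 0.792 / 0.500 / 0.684 / 0.731 / 0.583 at three
decimals, which pins down the counts behind such a published panel.

## What the synthetic generator does and does not emulate

`make_cc_mask` builds a half-annulus arch in the mid-sagittal plane
(outer radius 0.32 × the in-plane extent, inner radius 0.6 of that) with
seeded smooth ripples of both radii, extruded over exactly nine sagittal
slices; at the default 32×64×64 grid this yields roughly 3,500–4,000 ROI
voxels. `make_subject` fills the ROI with a Gaussian random field of stated
mean and SD whose in-plane correlation length is the class-contrast dial:
smoothing white noise with a Gaussian kernel of scale σ gives a lag-1
autocorrelation ≈ exp(−1/(4σ²)), so σ = 0 yields i.i.d. texture and σ = 3
a strongly coarse one. An optional multiplicative low-frequency field adds
heterogeneity. Class contrast is deliberately carried by texture
*coarseness*, not by mean intensity or mask shape — each subject's mask
perturbation is seeded independently of class — so discrimination must come
from co-occurrence/run-length features, mirroring the texture-heterogeneity
premise of CC radiomics. Covariates (age, education, MMSE, sex) are drawn
from the motivating cohort's published group summaries, with MMSE truncated
at the diagnostic inclusion bounds (cases ≤ 24; controls in [28, 30],
consistent with the near-ceiling published SD of 0.77).

The generator does **not** emulate MR physics (bias fields, Rician noise,
partial-volume effects), scanner or site variation, or real CC anatomy, and
its class contrast is a single controlled dial. Passing end-to-end tests
therefore demonstrates that the pipeline's machinery is correct and
leakage-free and that its operating characteristics are calibrated — not
that any particular clinical effect size is reproduced. Published headline
numbers that depend on the original images (a test AUC of 0.720; a
385→196→89→11 selection trajectory) are intentionally replaced by
property-based checks: oracle equivalence of every texture feature,
type-I calibration of the univariate filter, planted-support recovery of
the LASSO, a strong-contrast cohort achieving test AUC > 0.9, and a
100-replicate null calibration with mean test AUC within 0.5 ± 0.05.

## Problem sizes and numerical choices

The validation suite runs at deliberate desk scales chosen as the package's
own defaults: strong-effect cohorts of 30 + 30 subjects on 32×64×64 grids
(full 385-feature extraction), null-calibration replicates of 12 + 12
subjects at a reduced extraction configuration (offset 1, 8 gray levels —
the calibration concerns ranking, not the catalogue), and oracle checks on
12×12 single-slice ROIs. Seeds are fixed throughout; every stochastic stage
(split, folds, generator) takes an explicit seed, and the orchestrator
derives per-stage seeds from one master seed so stages are independently
reproducible. Degenerate and boundary cases (constant ROIs, empty masks,
clipped slabs, zero-variance columns, separation) are handled by the
explicit conventions above rather than by error suppression.

## Known limitations

* The 385-feature composition is a reconstruction; the original
  commercial software's exact catalogue is undocumented, so absolute
  feature values are comparable within this package only (it is not an
  IBSI-certified implementation).
* Texture is computed in-plane per sagittal slice; no 13-direction 3D
  texture is provided.
* No wavelet/filtered-image features, no confidence intervals on AUC, and
  no nested cross-validation for performance estimation — the evaluated
  split is a single stratified 70/30 partition by design.
* The separation fallback's small ridge makes coefficients finite but
  slightly biased; the flag should be checked before interpreting
  coefficients scientifically.
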