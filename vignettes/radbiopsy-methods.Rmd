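---
title: "Methods: MRI radiomics virtual biopsy for BRAF genotyping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MRI radiomics virtual biopsy for BRAF genotyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Roughly half of melanomas carry an activating BRAF mutation, and targeted
BRAF/MEK inhibition has transformed the management of metastatic disease. The
mutation status of a *brain* metastasis, however, can differ from that of the
primary tumor, and today it can only be established by tissue sampling.
`radbiopsy` implements a "virtual biopsy": a radiomics pipeline that predicts
the binary BRAF status of a melanoma brain metastasis from the routine
post-contrast T1-weighted MRI alone, together with a synthetic 3D cohort
generator so the entire analysis is testable at desk scale without any
clinical data.

The pipeline has four stages, each a package module:

1. **Normalization** (`normalize_to_reference()`): every voxel is divided by
   the mean intensity over a normal-appearing white-matter (NAWM) reference
   mask, putting scans from different vendors and field strengths on one
   intensity scale. The mean (not the median) is used: the reference region
   is by definition homogeneous, where the two coincide asymptotically, and
   the mean is the conventional reading of "normalization relative to" a
   region.
2. **Feature extraction** (`extract_features()`): a fixed, ordered vector of
   195 features per lesion — 2 clinical (age, gender), 16 atlas-location
   percentages, 9 morphology, 12 first-order histogram statistics, and
   12 gray-level co-occurrence (GLCM) measures x 13 offsets = 156 texture
   features.
3. **Screening and reduction** (`select_features()`, `fit_pca()`): per
   feature, a Kolmogorov-Smirnov gate decides between a pooled-variance
   t-test and a Mann-Whitney U test of the two BRAF groups; features with
   p < 0.05 are standardized (cohort mean / sample SD) and reduced by PCA to
   the components explaining 95% of the variance.
4. **Classification** (`cross_validate_svm()`, `run_pipeline()`): six SVM
   kernels (linear, quadratic, cubic, fine/medium/coarse gaussian) under
   patient-grouped, class-stratified 5-fold cross-validation, reported as
   per-class precision/sensitivity/specificity, accuracy, and pooled ROC/AUC.

## Texture features

The co-occurrence matrix for an offset direction $\mathbf{o}$ and distance
$d$ counts in-lesion voxel pairs $(v,\,v + d\,\mathbf{o})$, accumulated
symmetrically (each pair in both orders) and normalized to probabilities
$p(i,j)$ over quantized gray levels. Choices the source analysis left open,
declared here as fixed conventions:

- **Quantization**: 32 equal-width bins over the in-lesion intensity range
  (`glcm_config(n_levels = )`). Because binning is range-relative, scaling
  intensities by any positive constant leaves every texture feature
  unchanged (a tested invariant).
- **Offsets**: the 13 canonical non-antiparallel directions of the
  26-neighbourhood — the four in-plane angles 0/45/90/135 degrees plus nine
  out-of-plane directions. Symmetric accumulation makes an offset and its
  negation equivalent, so 13 directions cover all 26 neighbours.
- **Distance**: 8 voxels, applied as a per-component multiplier
  (displacement $= d \cdot \mathbf{o}$), not an equalized Euclidean length.
- **Degenerate case**: a lesion thinner than the displacement along an
  offset has no valid pairs; the GLCM is all-zero with `pair_count = 0` and
  all 12 measures are emitted as `NA`. Downstream selection reports such
  features as "undefined" and never selects them.
- **Entropy** uses log base 2 with $0 \log 0 \equiv 0$; `contrast` and
  `inertia` intentionally share one formula (both names appear in the
  measure inventory; common co-occurrence implementations define them
  identically), keeping the texture block at 12 x 13 = 156 entries.
- **Correlation** of a zero-variance (single-level) matrix is emitted as 0.

## Morphology

Computed on the largest 26-connected component (warning if the mask is
fragmented): volume, equivalent diameter $(6V/\pi)^{1/3}$, extent
(volume / bounding box), principal axis lengths $2\sqrt{5\lambda_i}$ from
the eigenvalues of the voxel-center covariance (population divisor, plus the
$s^2/12$ cell-spread term for voxel size $s$), convex volume, solidity, and
iso-surface area. Two components are authored in-package:

- the **3D convex hull** (quickhull with flattened face storage), voxelized
  to a convex image: convex volume = count of voxel
  centers inside the hull x voxel volume, so a digital cube has solidity
  exactly 1. Flat (rank-deficient) masks fall back to convex volume =
  volume with a warning.
- the **surface area** estimator, via the coarea formula: the mask
  indicator is smoothed with a small Gaussian (sigma 1.5 voxels) and the
  gradient magnitude integrated. Exact for planar interfaces; on a digital
  ball of radius 15 the error is about 0.1-0.5%, well inside the 10%
  validation band used by the tests. It mildly underestimates sharp edges
  (rounded corners), which is irrelevant at lesion scales.

First-order percentiles interpolate linearly between order statistics
(`quantile` type 7); kurtosis uses the non-excess convention (normal = 3)
and skewness/kurtosis the biased moment estimators, matching the numeric
environment of the original analysis. A zero-variance lesion emits 0 for
both, with a warning, to keep feature vectors numeric.

## Screening, standardization, PCA

The normality gate applies the one-sample KS test to z-scored values per
feature *per group*; the pooled-variance t-test is used only when both
groups pass at 0.05, otherwise the Mann-Whitney U with normal approximation
and tie correction. No multiplicity correction is applied by default —
deliberately replicating the original design — and a Benjamini-Hochberg
option (`adjust = "BH"`) is available but off.

Standardization uses the cohort mean and sample SD (divisor $n-1$);
zero-spread features are dropped with a warning. PCA eigendecomposes the
covariance of the standardized selected features; $k$ is the smallest
component count reaching 95% cumulative variance; eigenvalues below
$10^{-12}$ of the total are treated as numerical rank deficiency; component
signs are fixed by making each component's largest-magnitude loading
positive, so refits are bit-reproducible.

**Leakage is a first-class concept.** In `mode = "cohort_fit"`,
selection, standardization and PCA are fitted on the *whole* cohort before
cross-validation — the original study's design, in which label information
leaks from validation folds into the representation. In
`mode = "leakage_free"` all three are refitted inside each training fold.
Every report records its mode. The difference is not cosmetic: on null
cohorts (identical class parameters) the cohort-fit pipeline averages
AUC around 0.7 purely from selection leakage, while the leakage-free
pipeline sits at 0.5 as it should. For this reason the package's null
calibration is defined on the leakage-free mode, and cohort-fit results
should be read as reproducing the original protocol, not as unbiased
performance estimates.

## Classification conventions

- Gaussian kernel scales follow the fine/medium/coarse convention
  $\sqrt{P}/4$, $\sqrt{P}$, $4\sqrt{P}$ for $P$ input dimensions;
  quadratic/cubic are polynomial kernels of degree 2/3 with unit offset.
  Box constraint 1; no hyperparameter search, by design.
- Folds are assigned at the *patient* level (all lesions of a patient share
  a fold), stratified by class, patients dealt to the least-loaded fold
  after a seeded shuffle; 53 patients over 5 folds give sizes 11/11/11/10/10.
- The decision threshold is the SVM's natural 0. Undefined precision (a
  class never predicted) is reported as 0 with an explicit warning flag.
- Fold summaries use the mean and the *population* SD (divisor = number of
  folds): this is the convention that reproduces the published summary
  "0.72 +- 0.20" from the printed per-fold sensitivities (the sample SD
  gives 0.23). The printed per-fold table ships as
  `reference_fold_metrics()` and the arithmetic is asserted in the tests.
- ROC/AUC: threshold sweep over pooled validation-fold decision values;
  AUC equals the Mann-Whitney pairwise statistic with ties counting 0.5
  (identical to trapezoidal integration of the tie-grouped sweep, and
  asserted equal to exhaustive pair enumeration and to an independent ROC
  implementation in the tests). Per-fold AUCs are reported alongside.

## The synthetic cohort generator

The generator emulates the statistical structure the analysis assumes, not
brain anatomy. Defaults are the study conditions: 25 BRAF-positive and 29
BRAF-negative lesions on a 64^3 grid at 1 mm; ages N(55, 14^2) vs
N(64.4, 12.3^2) years; female fractions 9/25 vs 12/29; a 16-block grid atlas
standing in for the Talairach lobar parcellation; class-skewed location
priors (positive lesions favour right limbic / left parietal, negative left
frontal); ellipsoidal lesions with semi-axes drawn from 7-12 voxels
(1.4-2.4 cm diameter, the scale of surgically resected metastases — chosen
also so that every co-occurrence offset is sampled at displacement 8);
and a homogeneous reference block as the NAWM surrogate. All randomness
derives from one master seed through a counter-based scheme, so cohorts are
bit-reproducible across platforms; an optional flag gives one patient two
lesions to exercise patient-grouped folding.

**Texture.** Lesion texture is a Gaussian random field — seeded white noise
smoothed with a per-class correlation length — whose marginal is then
rank-mapped to a uniform distribution within the lesion (a Gaussian copula
construction) before scaling to the class's intensity SD. The uniformization
matters: with a raw Gaussian marginal and range-relative quantization, GLCM
entropy at displacement 8 is dominated by how far the sample extremes sit
from the bulk — an effective-sample-size artifact that can invert the
intended heterogeneity ordering between a smooth and a rough class. With
identical uniform marginals, co-occurrence differences between classes are
carried by spatial correlation structure alone, and the intended direction —
the shorter-correlation (BRAF-negative surrogate) class has higher GLCM
entropy — holds by construction. Defaults use correlation lengths 6
(positive) vs 1.5 (negative) voxels;
`strong_separation_config()` (8 vs 1, the positive class smooth at the
displacement scale) is the parameter-recovery condition under which the
linear-SVM pipeline is required to reach AUC >= 0.85;
`null_cohort_config()` equalizes every class parameter for calibration.

What the generator does **not** model: anatomy, MR physics, scanner and
vendor effects, partial-volume boundaries, necrotic cores, or any
morphology-genotype association. Passing tests on synthetic cohorts
demonstrate that the pipeline recovers the statistical structure it is
pointed at with calibrated error rates; they say nothing about how well
GLCM features capture real BRAF biology.

## Numerical and degenerate-input choices

- Grid alignment is asserted by shape and spacing equality; no resampling.
- An empty lesion or reference mask, a zero reference mean, a single-class
  cohort, or fewer patients than folds are hard errors with typed
  conditions.
- On null cohorts a training fold may select fewer than 2 features; the
  pipeline then falls back to the 2 smallest-p features (PCA needs two
  columns) with a warning rather than aborting a calibration run.
- Problem sizes in the test-suite calibration blocks: 1000 null features for
  the type-I check; 10 replicate 54-lesion cohorts each for the null and
  the recovery surfaces — sizes at which the Monte-Carlo error of an AUC
  mean is about 0.02-0.03, comfortably inside the asserted bands.

## Known limitations

- The published headline numbers (accuracy 0.79 +- 0.13, AUC 0.78, 50/195
  significant features, 9 components) belong to the original 54-lesion
  clinical cohort, which is not publicly deposited; they are not
  reproducible targets, and the package does not pretend otherwise. The
  package reproduces the printed fold-summary *arithmetic* exactly and the
  qualitative findings (heterogeneity direction) on synthetic cohorts.
- No IBSI compliance is claimed; the feature definitions follow the
  conventions above, not the IBSI reference.
- The skull stripping, tissue segmentation, manual tumor delineation and
  template registration that precede this pipeline clinically are out of
  scope: masks and atlas labels are inputs.
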