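# radbiopsy

MRI-radiomics "virtual biopsy" for melanoma brain metastases: predicting a
lesion's BRAF mutation status noninvasively from its routine post-contrast
T1-weighted MRI, instead of tissue sampling.

About half of melanomas carry an activating BRAF mutation, and the mutation
status of a brain metastasis — which can differ from the primary tumor's —
decides whether targeted BRAF/MEK inhibition is an option. `radbiopsy` turns
a contrast-enhanced 3D volume plus a lesion mask, a normal-appearing
white-matter (NAWM) reference mask, and a 16-region atlas into a fixed
195-feature radiomic profile, screens and reduces it, and classifies BRAF
status with cross-validated support vector machines. A seeded synthetic
cohort generator reproduces the statistical structure of the clinical
problem (class-dependent texture heterogeneity, location priors and
demographics) so the whole analysis runs, and is tested, at desk scale.

## The method

For each lesion, after dividing all intensities by the mean over the NAWM
reference:

| block | n | content |
|---|---|---|
| clinical | 2 | age, gender |
| location | 16 | % of lesion voxels per atlas region (left/right frontal, parietal, temporal, occipital, limbic, sublobar, cerebellum, brainstem) |
| morphology | 9 | volume, equivalent diameter, extent, 3 principal axis lengths, convex volume, solidity, surface area |
| first-order | 12 | mean, median, SD, variance, min, max, percentiles 5/25/75/95, kurtosis, skewness |
| GLCM | 156 | 12 Haralick measures (energy, entropy, correlation, contrast, variance, sumMean, inertia, cluster shade/tendency, homogeneity, maxProbability, inverse variance) × 13 offsets at voxel distance 8 |

Gray-level co-occurrence matrices are symmetric,
P(i,j) over 32 range-relative levels, one per canonical 3D offset direction
**o** at displacement 8·**o**. Features are screened per feature with a
KS-gated t-test / Mann–Whitney U (two-sided, α = 0.05, no multiplicity
correction), standardized as x_std = (x − x̄)/σ̂, reduced by PCA to the
components explaining 95% of variance, and classified by six SVM kernels
under patient-grouped stratified 5-fold cross-validation with per-class
precision / sensitivity / specificity, accuracy, and pooled ROC/AUC
(AUC = tie-aware Mann–Whitney pairwise statistic).

Both analysis modes are first-class: `cohort_fit` fits
selection/standardization/PCA on the whole cohort before cross-validation
(the original protocol, optimistically biased by design), `leakage_free`
refits them inside every training fold. Reports always state their mode.

## Worked example

```r
library(radbiopsy)

cfg     <- cohort_config(n_positive = 10L, n_negative = 12L, seed = 42L)
cohort  <- generate_cohort(cfg)                 # 22 synthetic subjects
features <- extract_cohort_features(cohort)     # 22 x (3 id cols + 195 features)
result  <- run_pipeline(features,
                        kernels = svm_kernels()[c("linear", "medium_gaussian")],
                        seed = 42L)
result
#> <pipeline_result> mode = cohort_fit, 22 lesions, 2 kernel(s)
#>   linear           accuracy 0.86 +- 0.12, AUC 0.96
#>   medium_gaussian  accuracy 0.91 +- 0.11, AUC 0.94

glance(result$selection)
#> # A tibble: 1 x 7
#>   n_features n_selected n_t_test n_mann_whitney n_undefined alpha adjust
#>        <int>      <int>    <int>          <int>       <int> <dbl> <chr>
#> 1        195         49      178             17           0  0.05 none

glance(result$pca)
#> # A tibble: 1 x 4
#>   n_features     k threshold cumulative_variance_k
#>        <int> <int>     <dbl>                 <dbl>
#> 1         49    10      0.95                 0.955

tidy(result$reports$linear)
#> # A tibble: 7 x 3
#>   metric           mean    sd
#>   <chr>           <dbl> <dbl>
#> 1 precision_pos   0.933 0.133
#> 2 sensitivity_pos 0.8   0.245
#> 3 specificity_pos 0.9   0.2
#> 4 precision_neg   0.883 0.145
#> 5 sensitivity_neg 0.9   0.2
#> 6 specificity_neg 0.8   0.245
#> 7 accuracy        0.86  0.116
```

Of the 195 features, 49 separate the classes at p < 0.05 (the synthetic
classes differ in texture correlation length, so most of these are GLCM
features); 10 principal components cover 95% of their variance; the linear
SVM then recovers the class structure with a pooled cross-validated AUC of
0.96. `autoplot(result$reports$linear)` draws the pooled ROC curve,
`autoplot(result$pca)` the variance profile, and
`autoplot(result$selection)` the per-feature p-value landscape.

Real cohorts enter through the same door: `read_cohort("dir/manifest.csv")`
reads a manifest of NIfTI paths (volume, lesion mask, NAWM mask, atlas) plus
age/gender/BRAF columns — the exact layout `write_cohort()` produces.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/radbiopsy.R synth --out cohort_dir --seed 7
Rscript inst/cli/radbiopsy.R run --manifest cohort_dir/manifest.csv --out results_dir --seed 7
```

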