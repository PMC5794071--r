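# roifuse

Multimodal ROI-level data fusion for case-control neuroimaging studies.

Case-control studies that acquire resting-state fMRI, structural MRI and
diffusion imaging on the same subjects usually analyze the three modalities
separately, and the three analyses often disagree. roifuse implements the
fusion-first alternative: for each region of interest (ROI) of the 90-region
AAL parcellation, it concatenates

- 89 functional-connectivity features (Pearson correlations with every other
  ROI, Fisher r-to-z transformed),
- grey- and white-matter volume, and
- the diffusion scalars FA, RD = (λ₂+λ₃)/2 and MD = (λ₁+λ₂+λ₃)/3

into one 94-wide multi-index vector, then

1. **screens** every ROI for group differences with Wilk's lambda
   λ = |W|/|T| and Bartlett's chi-square transform
   χ² = −(n − 1 − (G+m)/2)·log λ on m(G−1) degrees of freedom,
2. **classifies** the groups with a nested cross-validated SVM (in-fold
   t-test feature selection, kernel/cost grid tuned on a dedicated fold,
   repeated fold randomization, permutation-based significance),
3. **compares** classifiers via the Jaccard coefficient on
   correctly-classified subject sets and Cohen's kappa on predicted labels,
   and
4. **decomposes** the fusion signal into per-modality contributions as
   ratios of Cox-Snell R² = 1 − exp{2(ℓ₀−ℓ₁)/n} from logistic fits.

A synthetic two-group cohort generator with known effect locations and sizes
makes every stage testable without clinical data; it is first-class,
documented API.

The package is tidyverse-native: results come back as tibbles, fitted
objects have `tidy()`/`glance()` methods, and each result type has an
`autoplot()`.

## Worked example

Simulate a cohort of 2 × 40 subjects over 12 ROIs with a structural and a
diffusion effect planted at ROI 5, build and normalize the fusion features,
and screen all ROIs:

```r
library(roifuse)
library(dplyr)

sim <- generate_cohort(cohort_config(
  n_per_group = 40, n_roi = 12, n_timepoints = 150,
  effects = data.frame(roi = 5, modality = c("gm", "fa"), d = 0.9),
  seed = 1))

fs <- fusion_features(sim$cohort) |> zscore_normalize()
screen <- screen_rois(fs, sim$cohort$labels)
screen |> arrange(p) |> head(3)
#> # A tibble: 3 × 9
#>     roi measure     m lambda  chi2    df         p neglog10p reason
#>   <int> <chr>   <int>  <dbl> <dbl> <dbl>     <dbl>     <dbl> <chr>
#> 1     5 fusion     16  0.490  49.9    16 0.0000241      4.62 <NA>
#> 2     5 smri        2  0.785  18.6     2 0.0000912      4.04 <NA>
#> 3     5 dti         3  0.799  17.1     3 0.000668       3.18 <NA>
```

The planted ROI attains the smallest p, and the fusion measure (here 11 FC +
2 sMRI + 3 DTI = 16 features) beats the single-modality measures at that
ROI. `tally_best_measure(screen)` counts winners per measure set, and
`autoplot(screen)` draws the per-ROI −log₁₀(p) profile.

Classify the same cohort from the fusion design and decompose the signal:

```r
cfg <- classifier_config(kernels = c("linear", "radial"),
                         c_grid = c(0.1, 1, 10), n_repeats = 5, seed = 2)
report <- nested_cv(measure_design(fusion_features(sim$cohort), "fusion"),
                    sim$cohort$labels$group, cfg)
report
#> <cv_report> 10-fold nested CV, 5 repeat(s)
#>   accuracy 0.6200 (sd 0.0420), sensitivity 0.6150, specificity 0.6250, AUC 0.7019

contribution_ratios(fs, sim$cohort$labels)
#> # A tibble: 4 × 3
#>   model     r2  ratio
#>   <chr>  <dbl>  <dbl>
#> 1 fusion 0.750 NA
#> 2 fmri   0.750  1.000
#> 3 smri   0.455  0.606
#> 4 dti    0.741  0.988
```

Out-of-fold accuracy reflects the modest planted effect (two features at
d = 0.9 inside a 16-wide fusion vector). The contribution table is
*in-sample* goodness of fit: at 80 subjects the 132-column pooled fMRI
design fits the labels up to the Cox–Snell ceiling 1 − exp(2ℓ₀/n) = 0.75
even though no functional signal was planted — wide modality blocks inflate
their own contribution, which is exactly why the ratios must be read as
goodness-of-fit shares at the given widths, not as ground-truth signal
location (see the methods vignette).

`run_pipeline(run_config(...))` chains
simulate → fuse → screen → classify → concord → contribute and writes
`screen.csv`, per-measure report JSONs, `predictions.csv`, `concord.csv`,
`contrib.json` and a seed/hash manifest to an output directory; a thin
`exec/roifuse` script exposes `simulate` and `run` from the shell with a
YAML configuration.

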