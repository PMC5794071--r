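---
title: "Multimodal ROI-level fusion: models, screening and classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal ROI-level fusion: models, screening and classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(roifuse)
library(dplyr)
```

## The problem

Case-control neuroimaging studies routinely acquire three views of the same
brain: resting-state fMRI (dynamics), structural MRI (tissue volumes) and
diffusion imaging (white-matter microstructure). Analyzed separately, each
modality tests a different projection of the underlying pathology and the
three analyses often disagree. roifuse implements a *fusion-first* strategy:
for every region of interest (ROI) of a 90-region AAL parcellation, the three
modalities' regional summaries are concatenated into one multi-index vector
and group differences are tested, classified and decomposed on that joint
vector.

Per ROI, the fusion vector holds

* 89 functional-connectivity (FC) features — Pearson correlations of the
  ROI's BOLD time series with every other ROI, Fisher r-to-z transformed;
* 2 structural features — grey-matter (GM) and white-matter (WM) volume;
* 3 diffusion features — fractional anisotropy (FA), radial diffusivity
  (RD = (λ₂+λ₃)/2) and mean diffusivity (MD = (λ₁+λ₂+λ₃)/3), computed from
  the tensor eigenvalues λ₁ ≥ λ₂ ≥ λ₃.

That is 94 features per ROI, z-normalized column-wise so no modality
dominates by scale alone. Optionally the FC block is replaced by its first
`k` principal components (default `k = 5`, giving a 10-wide vector), which
matters for the screening comparison below.

## Group screening: Wilk's lambda

For `G` groups with `n_g` subjects and an `m`-wide measure vector per
subject, the within-group (`W`), between-group (`B`) and total (`T = W + B`)
dispersion matrices give Wilk's lambda

$$\lambda = \frac{|W|}{|T|} \in (0, 1],$$

small when group means separate relative to within-group scatter. P-values
come from Bartlett's large-sample transform
$\chi^2 = -(n - 1 - (G + m)/2)\,\log\lambda$ with $m(G-1)$ degrees of
freedom. Determinants are evaluated on the log scale; a singular `T` (or
`n - G < m`) is reported as an explicit error with an optional ridge fallback
(`W + \epsilon I`, `T + \epsilon I`, `\epsilon = 10^{-8}\,\mathrm{tr}(T)/m`),
which is off by default because a regularized lambda is a diagnostic, not the
test statistic.

`screen_rois()` runs this per ROI for any subset of the four measure sets
(fMRI, sMRI, DTI, fusion) and `tally_best_measure()` counts which measure
attains the smallest p per ROI. Exact ties — possible in principle, rare in
floating point — are broken by the fixed precedence fusion > fMRI > sMRI >
DTI with a warning, so tallies are reproducible.

Two numerical cautions shaped the defaults:

* **Bartlett at large m.** With `m = 94` and a few hundred subjects the
  chi-square approximation is visibly anti-conservative (we measured ~9%
  rejection at the 5% level in null simulations at `n = 200`). The
  calibration and recovery simulations in the test suite therefore run the
  fusion screen at the PCA-reduced width (`m = 10`), where the approximation
  is accurate. The full-width screen remains available and correct for the
  sample sizes that justify it.
* **Dilution at full width.** An effect confined to two coordinates (say GM
  and FA) is diluted by the 89 null FC coordinates of the full fusion
  vector, and the focused 2-wide sMRI test can beat the 94-wide fusion test.
  After PCA reduction the fusion vector is 10-wide and recovers its
  advantage. This mirrors the empirical observation that best-measure
  tallies favour fusion much more strongly after PCA reduction.

## Univariate utilities

`pooled_t_test()` accepts either raw samples or printed `(mean, sd, n)`
summaries, so demographic tables from published work can be checked directly;
`pearson_chi2_2x2()` is the uncorrected chi-square on a 2×2 count table.
For `m = 1, G = 2`, Wilk's lambda reduces exactly to
$1/(1 + t^2/(n-2))$ with `t` the pooled two-sample statistic — a closed-form
bridge the tests exploit.

## Classification: nested cross-validation

`nested_cv()` implements a 10-fold cross-validation with three fold roles:
eight folds train, one tunes, one tests, rotated over all ten folds. Inside
each training partition — and only there — features are z-normalized and
selected by a two-sample t-test (`selection_alpha = 0.05`; the threshold is
a screening device, not an inference), then an SVM (libsvm via e1071) is fit
for every kernel in `{linear, polynomial, radial}` × cost in
`{10^-3 … 10^4}`; the tuning fold picks the winner by accuracy and the test
fold is scored once. The assignment is re-randomized `n_repeats` times
(default 100; simulations in the tests and the acceptance script use 2–5
repeats, which leaves the mean accuracy estimate's precision at the level
the assertions need while keeping runtimes in seconds).

Choices the underlying description leaves open, fixed here:

* Fold repeats re-randomize the stratified fold assignment (not bootstrap
  resampling).
* The polynomial kernel degree is fixed at 3 (configurable).
* Reported accuracy is the plain proportion correct pooled over out-of-fold
  predictions; sensitivity/specificity are taken with the second factor
  level as positive class unless overridden.
* Normalization/selection/PCA are refit per training partition by default to
  avoid information leakage. A `paper_mode` switch in `run_config()` instead
  normalizes once globally, mirroring pipelines that do not document
  fold-wise refitting; the leakage-free default is the package's
  recommendation, and a dedicated test verifies that 200 noise features at
  `n = 40` stay at chance accuracy under it.

`permutation_test()` reruns the full nested CV on label-permuted data and
uses the add-one estimator `p = (1 + #{perm ≥ obs})/(1 + P)`, so `p` is
never 0 and the smallest attainable value at `P = 100` is 1/101.
`roc_auc()` is the rank-based (Mann-Whitney) AUC with ties counted half,
and the returned ROC polygon integrates (trapezoid) to exactly that number.
`compare_accuracy_distributions()` contrasts two classifiers' per-repeat
accuracies, paired by default when fold seeds are shared.

## Concordance and contribution

Two classifiers are compared by (a) the Jaccard coefficient between their
sets of correctly-classified subjects — with `J = 1` for two empty sets, and
an alternative predicted-positive-set variant behind a flag — and (b)
Cohen's kappa between their predicted-label vectors, treating the
classifiers as two raters. Since repeated CV yields 100 predictions per
subject, `consensus_predictions()` first majority-votes per subject; exact
ties go to the positive class and are logged.

Modality contribution is quantified by logistic regression: with features
`X` (all ROIs' columns of one modality pooled into a single design — the
pooling is a deliberate, documented choice), the Cox-Snell index

$$R^2 = 1 - \exp\{2(\ell_0 - \ell_1)/n\}$$

compares the fitted and intercept-only log-likelihoods, and each modality's
contribution is `R²_modality / R²_fusion`. The logistic fit is a Newton
iteration with step-halving, converged at gradient norm `1e-8`; at the
94-feature fusion width quasi-complete separation is a real possibility, so
the default ridge is `1e-4` (the penalty is excluded from the reported
likelihoods) and an unpenalized fit that separates is an explicit error, not
a silently absurd ratio.

One caveat deserves emphasis: Cox-Snell R² is an *in-sample* index, and a
wide modality block can fit the labels well — up to the ceiling when columns
approach the subject count — whether or not it carries true signal. The fMRI
block is 89/94 of the fusion width, so part of its large contribution ratio
is structural. Ratios are therefore goodness-of-fit shares at the given
block widths, to be read alongside the screening and classification results
rather than as ground-truth signal localization; the README's worked example
shows the saturated regime deliberately.

## The synthetic cohort generator

No clinical data ships with the package; `generate_cohort()` creates
two-group cohorts in which every downstream claim is checkable against known
ground truth:

* **BOLD series** are Cholesky-colored i.i.d. Gaussian innovations with a
  target ROI×ROI correlation matrix (default exchangeable, ρ = 0.1) — the
  stated pairwise correlations hold in population, with *no temporal
  autocorrelation*: band-pass structure, hemodynamics, motion and scanner
  noise are deliberately out of scope.
* **Scalar modalities** are Gaussians with field-plausible baselines (GM
  7.5 ± 1.2 cm³, WM 5.0 ± 1.0 cm³, FA 0.45 ± 0.05, RD 0.60 ± 0.06 and MD
  0.80 ± 0.06 ×10⁻³ mm²/s per ROI); group-2 means shift by `d` pooled SDs at
  affected ROIs.
* **FC effects** are edits to group 2's target correlation matrix (rejected
  if the edit breaks positive definiteness), so injected connectivity signal
  flows through the entire Fisher-z feature pipeline rather than being
  pasted onto features.
* One master seed fans out to per-subject streams, so enlarging the cohort
  never reshuffles existing subjects, and equal seeds give bit-identical
  cohorts.

Because the generator's draws are independent across subjects and Gaussian
within modality, passing tests demonstrate correctness of the statistical
machinery — calibration, recovery, ordering — not robustness to the
artefacts of real imaging (registration error, site effects, heavy tails,
temporal autocorrelation).

The default study conditions used by the test-suite simulations: null
calibration on cohorts of 100 subjects per group (90 ROIs, 150 time points,
about 2000 per-ROI tests pooled across cohorts); effect recovery at
`n = 150` per group with a total Mahalanobis shift of `d = 1` split evenly
over GM and FA at a single ROI; contribution recovery with
functional-connectivity deltas of 0.3–0.35 on a few ROI pairs. These sizes
give the assertions comfortable power while each simulation completes in
minutes on one core.

## Known limitations

* Bartlett's chi-square is the only Wilks transform provided; exact F
  transforms and the Pillai/Hotelling-Lawley/Roy statistics are out of
  scope.
* The classifier suite is binary SVM only, with plain accuracy (no
  reweighting under class imbalance).
* The CCA confound screen handles a single continuous covariate (where the
  maximal canonical correlation equals a multiple correlation and Bartlett's
  test applies directly).
* Cox-Snell is the only pseudo-R²; it cannot reach 1 and its ceiling
  `1 - exp(2ℓ₀/n)` depends on class balance, which is why only *ratios*
  between models on identical subjects are interpreted.
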