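---
title: "Grey-matter radiomics for ECT response prediction: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grey-matter radiomics for ECT response prediction: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Electroconvulsive therapy (ECT) combined with antipsychotics is an effective
treatment for severe or treatment-resistant schizophrenia, but roughly half of
patients do not respond, and the treatment carries real burden and risk. A
baseline biomarker of likely response would therefore be clinically valuable.
This package implements a radiomics pipeline that predicts response — defined
as a reduction of at least 70% in the PANSS total score from baseline, a
deliberately stringent criterion — from baseline structural MRI: modulated,
DARTEL-normalised grey-matter (GM) volume maps, one per subject, all on a
common voxel grid. The pipeline consumes those maps; tissue segmentation,
normalisation and Jacobian modulation happen upstream and are out of scope.

Because clinical cohorts of this kind are private, the package ships a
synthetic-cohort generator as a first-class, tested module. All statistical
machinery is exercised end-to-end on synthetic cohorts whose shape mirrors the
motivating study: 57 patients (28 responders, 29 non-responders), randomly
split into a training set of 44 (22 + 22) and a validation set of 13 (6 + 7).

## Pipeline overview

1. **ROI discovery** (`voxelwise_t_map()`, `threshold_clusters()`,
   `annotate_rois()`): a voxelwise pooled-variance two-sample *t*-test
   (df = n1 + n2 − 2, no covariates) between responders and non-responders on
   the *training set only*; two-tailed thresholding at *P* < .05 uncorrected;
   connected suprathreshold clusters of ≥ 100 voxels become regions of
   interest (ROIs). Positive and negative excursions are clustered separately
   and never merge. Each ROI is labelled with the atlas region covering
   strictly more than 50% of its voxels, else "unassigned".
2. **Feature extraction** (`first_order_stats()`, `feature_matrix()`): 15
   first-order histogram statistics per ROI per subject — mean, median,
   minimum, maximum, range, standard deviation, variance, mean absolute
   deviation, interquartile range, root mean square, energy, skewness,
   kurtosis, uniformity and entropy — concatenated in fixed ROI-then-statistic
   order. With 19 ROIs this gives the 285 features per subject the design
   anticipates.
3. **Standardization** (`fit_standardizer()`, `apply_standardizer()`): each
   feature is centred and scaled to unit sample variance using parameters
   estimated on the training subjects only; the validation set is transformed
   with the training parameters and never refitted.
4. **Classification** (`run_loocv()`): leave-one-out cross-validation over the
   training set. In each fold, features are filtered by an in-fold two-sample
   *t*-test (*P* < .05, computed without the held-out subject), then a
   LASSO-penalised logistic regression is fitted; a linear SVM refit on the
   fold's LASSO-selected features replicates the result with an independent
   classifier. Training performance comes from the 44 held-out predictions;
   validation performance averages the per-fold-model threshold metrics, while
   the validation ROC/AUC is computed from per-subject scores averaged across
   fold models (so the validation accuracy need not be a multiple of 1/13).
5. **Distillation and fusion** (`selection_frequency()`,
   `select_fixed_features()`, `fit_fixed_lrm()`, `build_fusion_model()`):
   features selected by LASSO in strictly more than 50% of the 44 partitions,
   truncated to the top three, define a fixed unpenalised logistic model;
   clinical covariates (baseline PANSS negative score, antipsychotic dose in
   olanzapine equivalents) are added and screened — first by variance
   inflation factor (drop the worst while any VIF ≥ 4), then by Wald
   coefficient tests (drop while any clinical *p* ≥ .05, largest first).
   Radiomic features are never dropped; removing every clinical covariate is a
   legitimate outcome.
6. **ROC comparison** (`delong_paired()`, `delong_unpaired()`): DeLong
   structural-components tests. Training-versus-validation comparisons use the
   unpaired form (disjoint subject sets, zero covariance); two score sets on
   the same subjects use the paired form with the covariance term.

`run_pipeline()` executes all stages from one configuration object and one
master seed; `rerun_excluding()` repeats the identical analysis after dropping
named subjects (keeping the original train/validation membership) and reports
the change.

## Key parameters

| Parameter | Default | Meaning |
|---|---|---|
| `p_threshold` | 0.05 | two-tailed voxel significance for cluster forming |
| `extent_threshold` | 100 voxels | minimum cluster size for an ROI |
| `connectivity` | 18 | cluster neighbourhood (6, 18 or 26); 18 is the SPM convention |
| `n_bins` | 64 | histogram bins for uniformity/entropy, spanning the ROI's own [min, max] |
| `alpha` | 0.05 | in-fold univariate filter level |
| `lambda_selection` | `"min"` | LASSO penalty by inner 5-fold CV deviance minimum; `"1se"` or a fixed value |
| `svm_cost` | 1 | linear-SVM soft-margin cost |
| `freq_threshold`, `k_fixed` | 0.5, 3 | strict selection-frequency cutoff and fixed-model size |
| `decision_threshold` | 0.5 | probability cutoff for confusion metrics (SVM uses decision value ≥ 0) |
| `vif_limit` | 4 | multicollinearity limit; removal at VIF ≥ 4 |

Where the upstream analysis choices are not documented anywhere (analysis
mask, tail convention, connectivity, histogram binning, LASSO tuning, SVM
cost), they are exposed as configuration with the defaults above: an implicit
mask at mean GM > 0.1 (the standard VBM heuristic), two-tailed thresholding
with sign-separated clusters, 18-connectivity, per-ROI histogram anchoring,
inner-CV deviance-minimising lambda, and C = 1. Moments use the population
convention (divisor *n*) and kurtosis is non-excess (normal ≈ 3), the common
radiomics convention; the standardizer uses the sample convention (divisor
*n* − 1), matching standard practice for z-scoring.

The responder criterion is *inclusive* (≥ 70% reduction): the cited
convention for elevated response thresholds reads the boundary as attained.
The 50% selection-frequency rule is *strict* (> 0.5), so a feature selected in
exactly half the partitions is excluded. Train/validation counts default to
22 + 22 / 6 + 7: the stated 3:1 ratio and the explicit counts are mutually
inconsistent (43:14 or 42:15 would round from 3:1), and explicit counts win.

## The synthetic cohort generator

`synthesize_cohort()` emulates the study conditions, not neuroanatomy:

- **Atlas**: an ellipsoidal "brain" mask partitioned into R contiguous
  regions (default 12; 90 fits a 48³ grid) by k-means on voxel coordinates —
  each cell is a Voronoi cell of its centre, hence connected.
- **Maps**: a smooth shared base template (≈ 0.55 GM fraction inside the
  mask) plus subject noise: white Gaussian noise smoothed to FWHM 3 voxels
  and rescaled so the in-mask per-voxel SD equals `noise_sd` (default 0.08 GM
  fraction). Responders gain `effect_size * noise_sd` inside the effect
  regions (default: 3 regions, d = 2), so `effect_size` is a true
  per-voxel standardized mean difference. Smoothing matters: spatial
  autocorrelation is what makes cluster-extent thresholding meaningful.
- **Clinical table**: fields drawn per group from published group summaries
  (responder baseline PANSS total 94.1 ± 19.2, antipsychotic dose 17.5 ± 5.9
  vs 13.8 ± 6.7 mg/d olanzapine equivalents, and so on). Covariates are
  sampled independently per field — the source reports only marginals — except
  that the PANSS total is the sum of its generated subscales. The percentage
  PANSS reduction is drawn per group (84.7 ± 9.6 vs 51.0 ± 12.8) and truncated
  half a point clear of the 70% criterion, so derived labels always match the
  intended group even after subscale rounding. Scale variables are clipped at
  a floor of one scale point rather than resampled; the induced mean bias is
  below 0.2% of the PANSS total.

What the generator does *not* emulate: tissue priors and anatomy,
scanner/site effects, covariance between clinical variables, longitudinal
post-ECT change, or any coupling between clinical covariates and the imaging
signal. Passing tests therefore demonstrate that the machinery is correct and
leakage-free under known ground truth — not that the clinical effect sizes
are attainable on real data.

## Numerical choices

- AUC is computed as the Mann–Whitney statistic with midrank tie handling;
  the empirical ROC polyline integrates (trapezoids) to exactly the same
  value, which is asserted to 1e-12 in the tests.
- DeLong variance uses the structural components (V10, V01) computed via
  midranks; identical score vectors give Δ = 0, p = 1 by convention. The
  unpaired form converts z with the standard normal; pROC's unpaired variant
  uses a Welch t instead, so the cross-check in the tests compares the z
  statistic exactly and the p value approximately.
- Confusion-metric ratios with zero denominators are reported as missing
  (`NA`), never as 0.
- glmnet fits use `standardize = FALSE` (the matrix is already standardized)
  and a warm-start path ending at the chosen lambda with a 1e-12 convergence
  threshold, so the solution satisfies the LASSO KKT conditions to 1e-6.
  With a single surviving feature a zero dummy column (provably never
  selected) satisfies glmnet's two-column minimum.
- A voxel with zero pooled variance has no t statistic; it is dropped from
  the analysis mask and counted.
- kmeans atlas partitions occasionally trigger the Hartigan–Wong
  Quick-TRANSfer advisory on large grids; the partition is still valid and
  the advisory is muffled.
- Ties in the selection-frequency ranking break by mean absolute coefficient
  across selecting folds, then by feature name, so rankings are fully
  deterministic.

## Determinism

One master seed drives everything. Stage seeds (atlas, template, maps,
clinical, split, LOOCV, per-fold inner CV) derive from it by hashing the
stage name (FNV-1a, reduced below 2³¹), so any stage can be rerun in
isolation with identical randomness, and two runs of `run_pipeline()` with
the same configuration produce byte-identical artifacts. Every output file
records the seed and an 8-hex-digit configuration hash.

## Test problem sizes

The suite builds every fixture programmatically. The heavier checks run at
these sizes, chosen once as a balance between statistical resolution and a
suite that runs in minutes on one CPU: planted-effect recovery uses 20
cohorts of 57 subjects on a 32³ grid with a 12-region atlas, d = 2 in 3
regions; the permutation-null calibration uses one null (d = 0) cohort with
44 balanced training subjects and 19 regions (285 features) and 50 label
permutations; DeLong type-I calibration uses 100 simulated null score pairs
of 60 subjects each; oracle equivalences use 10³–12³ grids and 20–60-subject
score sets.

## Known limitations, and one deliberate red flag

**Null LOOCV accuracy sits below 0.5.** Under label permutation the mean
held-out accuracy of the full filter + LASSO LOOCV is ≈ 0.43, not 0.5, and
the test suite's two-sided calibration check fails by design rather than
being weakened. Two well-understood mechanisms produce this, and both are
properties of a *correctly* leakage-free pipeline:

1. *Selection anti-bias*: in a null cohort, a feature chosen because it
   separates the n − 1 remaining subjects must, by exchangeability, lean the
   held-out subject toward the wrong side — the classic conservative bias of
   honest feature selection inside cross-validation.
2. *Balanced-majority artifact*: when no feature survives selection the model
   predicts the training prevalence; with an exactly balanced training set,
   leaving one subject out always makes the held-out subject's own class the
   minority, so every intercept-only fold predicts wrongly.

The important direction — accuracy *above* chance under the null, which would
indicate leakage or manufactured signal — is separately asserted and holds.
Readers comparing LOOCV accuracies near 0.5 on real data should keep this
conservative bias in mind.

Other limitations: validation aggregation follows the metric-averaging /
score-averaging reading of "averaged classification results", with per-model
numbers persisted for transparency; standardization is fitted once on the
full training set (the stage ordering of the upstream design), with the
strictly-per-fold alternative available via `fit_standardizer()` inside a
custom loop; the SVM reuses fold-specific LASSO selections (a global-set
reading is possible); and perfect separation in strongly separable synthetic
cohorts makes fusion-stage Wald tests uninformative, which the separation
flag records.
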