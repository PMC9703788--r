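---
title: "Identifying and validating structural-MRI biomarkers with searchmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying and validating structural-MRI biomarkers with searchmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(searchmark)
```

## The problem

Essential tremor (ET) and Parkinson's disease (PD) are the two most common
movement disorders and are frequently confused at presentation.  Voxel-based
morphometry (VBM) compares smoothed gray-matter (GM) volume maps between
patient groups and controls voxel by voxel, but mass-univariate statistics
cannot classify individual patients and say little about the joint,
multi-voxel structure of disease effects.  `searchmark` implements a
three-level multi-voxel pattern analysis (MVPA) framework for this setting:

1. **Model level** — a spherical searchlight slides over every in-mask
   voxel; the GM values inside the sphere are the features of a local
   PCA+SVM classifier of patients versus normal controls (NC), and the
   voxel is scored by its cross-validated decoding accuracy.  Thresholding
   the accuracy map (accuracy > 70%) with a cluster-extent filter
   (≥ 50 voxels, 26-connectivity) yields candidate regions.
2. **Feature level** — candidate clusters are split along the boundaries of
   a parcellation atlas (AAL-style), because a high-accuracy cluster that
   straddles an anatomical boundary is often driven by edge effects.  Each
   sub-cluster is re-scored on its own voxels and subjected to a label
   permutation test; sub-clusters with empirical `p <= 0.01` and extent
   `>= 50` voxels form the biomarker mask.
3. **Patient versus patient** — ET and PD subjects are classified from the
   biomarker-mask features and, for comparison, from all in-mask GM voxels,
   with a five-classifier panel (random forest, linear SGD, bagged trees,
   Gaussian naive Bayes, PCA+SVM) under repeated stratified
   cross-validation, reporting sensitivity, specificity, balanced accuracy
   and rank AUC.

A classical statistics branch (`fit_glm_tmap()`, `threshold_tmap()`,
`cluster_report()`) complements the MVPA chain: a voxelwise two-sample
t-test with age, sex and total intracranial volume (TIV) regressed out,
thresholded at one-tailed `p < 0.001` uncorrected with cluster extent ≥ 50.

## The permutation test

For a sub-cluster with observed cross-validated accuracy
$\mathrm{acc}(f, D)$ and $k$ accuracies recomputed on label-randomised
copies $D'$ of the data, the empirical p-value is the add-one estimator

$$
p = \frac{\left|\{D' : \mathrm{acc}(f, D') \ge \mathrm{acc}(f, D)\}\right| + 1}{k + 1}.
$$

The comparison uses `>=` with exact float equality — CV accuracies are
rationals with small denominators, so no tolerance is needed — and the
smallest attainable p is $1/(k+1)$; `permutation_config()` therefore
rejects `k` too small to reach the requested threshold.  `k` defaults to
999 (resolution 0.001 at the default threshold `p <= 0.01`); the test suite
uses `k` of 99–199 so calibration checks stay fast.  Each randomisation
shuffles the subject labels once and re-stratifies the fold assignment on
the permuted labels, the strictest exchangeability scheme consistent with
rerunning the identical protocol on a randomised copy of the data.  No
correction across sub-clusters is applied — a deliberate property of the
framework the package reproduces, and worth keeping in mind when reading
reports with many sub-clusters.

## Classifier protocol and its numerical choices

All decoding stages share one protocol (`cv_pca_svm()`): features are
centred and scaled by training-fold statistics, projected onto principal
components fitted on the training rows only — retaining the smallest
number of components whose cumulative explained variance reaches 80% (at
least one) — and classified with a linear SVM (`C = 1`).  Accuracy is the
plain fraction correct averaged over stratified folds; group sizes are
near-balanced by design, so no reweighting is applied at this stage.

Three choices deserve justification:

* **PCA inside the folds.**  Fitting the PCA on all subjects before
  splitting leaks test information into the features and inflates what an
  "accuracy > 70%" threshold means.  The `pca_leaky = TRUE` flag
  reproduces the naive variant for comparison.
* **Linear kernel.**  With 30-odd subjects and a handful of sphere voxels a
  linear decision function is the only well-posed choice, and is the MVPA
  norm.
* **One fold assignment per map.**  The searchlight reuses a single seeded
  stratified fold assignment for every centre, so fold noise is shared
  across the map (the map is smooth in the fold-noise sense) and the whole
  map is bit-reproducible from its seed.  The linear-SVM decision values
  are computed directly from the primal weights, which is algebraically
  identical to the library prediction path but much faster in the
  voxel-by-voxel loop.

The searchlight radius is interpreted in world millimetres (2 mm default):
with 2 mm voxels the sphere is the centre plus its six face neighbours
(7 offsets), with 1 mm voxels 33 offsets.  Spheres are truncated at the
mask boundary rather than skipped, matching searchlight practice and
avoiding an all-zero rim.  Whether the radius should count world mm or
voxel units is genuinely ambiguous in the framework's description; mm was
chosen and the parameter is configurable.

In the metric set, *accuracy* is the arithmetic mean of sensitivity and
specificity (balanced accuracy), with sensitivity the fraction of patients
correctly classified and specificity the fraction of the comparison group
correctly classified; `auc_rank()` is the Mann–Whitney form
$\mathrm{AUC} = (\sum_{i \in \mathrm{pos}} \mathrm{rank}_i - P(P+1)/2)/(PQ)$
with mean ranks for ties, and `roc_curve()` is the standard threshold
sweep whose trapezoidal area equals the rank form to numerical precision.
Hyperparameter optimisation is available as a seeded random search nested
inside training folds (`eval_protocol(hpo = "random")`); the default is
fixed, documented settings so results are deterministic and fast.  ROC
scores are signed decision values for the margin classifiers (SVM, SGD)
and positive-class probabilities for the probabilistic ones (forest,
bagging, naive Bayes).

## The synthetic cohort generator

No public imaging data accompany this framework, so validation runs on
synthetic cohorts whose statistical structure matches what the analysis
assumes.  `make_atlas()` partitions an ellipsoidal "brain" into contiguous
Voronoi parcels (with a few Lloyd relaxation steps so parcel sizes stay
comparable); `simulate_cohort()` builds each subject as

> baseline + group effect + TIV confound + voxel noise, then Gaussian
> smoothing,

with i.i.d. Gaussian noise before smoothing — smoothing then induces the
spatial correlation real VBM maps show.  Covariates (age, sex as 0/1, TIV
in ml) are drawn per group.  `default_scenario()` fixes the study
conditions: 17 NC, 15 ET, 16 PD; ages ≈ 53.3 / 56.6 / 69.1 y; TIV ≈
1360 / 1297 / 1427 ml; male proportions from the reported sex ratios (the
ET ratio 6/8 totals 14 where the group size is 15 — an inconsistency in
the source demographics; the proportion 6/14 is used with n = 15); ET
affected in four parcels, PD in two, overlapping in one, so the ET
pattern is the broader one.  Intensities are arbitrary "GM density" units
on $[0, \infty)$ — smoothed modulated VBM values are not probabilities, so
nothing is clipped to $[0,1]$.

Spatial scale required care.  The grid (default $18^3$ voxels at 1.5 mm)
is a desk-scale stand-in for a $121 \times 145 \times 121$ normalized
brain, but the generative premise — group differences confined to
designated parcels — must survive smoothing.  Real AAL parcels are several
6 mm-kernel widths across; a 6 mm kernel on an 18-voxel grid would be as
wide as a parcel and would smear every effect across its neighbours.  The
scenario therefore smooths at 2 mm FWHM (≈ 1.3 voxels) and erodes the
effect support one Chebyshev voxel into the parcel interior, keeping the
parcel-to-kernel width ratio comparable to the real setting.  (The
generic `sim_config()` default remains 6 mm, the conventional VBM
choice, for simulations at realistic grid sizes.)  The TIV-to-intensity
slope defaults to $10^{-4}$ intensity/ml: large enough that covariate
regression in the GLM branch is non-vacuous (per-subject global shifts of
about half the smoothed noise sd), small enough that the
covariate-blind MVPA stages — faithful to the framework, which regresses
covariates only in its statistical branch — are not globally confounded.
Sex is simulated but carries no effect, existing purely so covariate
regression is exercised.

What the generator does **not** emulate: cortical geometry, registration
error, multi-site effects, spatially varying noise, and any nonlinear
TIV–GM relationship.  Passing tests therefore show that the pipeline
recovers parcel-localised effects under its own assumptions — not that it
would behave identically on clinical data.

Effect sizes for the real cohorts are unknown; the default
`delta_scale = 10` (effect = 10 × voxel noise sd) is chosen for
testability, with `delta_scale = 0` providing exchangeable null cohorts
for calibration.

## Degenerate inputs and tie-breaking

* Voxels with zero variance across subjects get `t = 0` and can never be
  supra-threshold.
* Cluster peaks are the voxel of maximal `|statistic|`, ties broken by the
  lexicographically smallest (x, y, z) index, so reports are deterministic.
* Cluster extent uses `size >= min_size` (the framework's prose says ≥ 50
  while its figure captions say > 50; ≥ is implemented and `min_size` is
  configurable).
* Background-label sub-clusters are scored but excluded from the biomarker
  mask by default (`include_unlabeled = TRUE` overrides), since the point
  of the grouped analysis is respecting anatomical boundaries.
* Smoothing uses reflect padding and kernels truncated at 4σ and
  renormalised, so constants are preserved exactly and results are
  bit-reproducible.
* Rank-deficient design matrices (e.g. a constant covariate) fail with the
  offending column named rather than silently pivoting.

## Problem sizes used in the shipped checks

The package validates itself on sizes a laptop handles in minutes: null
calibration pools ≥ 100 sub-cluster permutation tests (k = 199) over five
$14^3$ cohorts; searchlight chance level uses 200 sampled centres and
recovery a full $18^3$ map; the end-to-end parcel-recovery check runs ten
seeded pipelines at k = 99.  Larger grids, parcel counts and k are purely
a matter of runtime.

## Worked example

```{r example, eval = FALSE}
library(searchmark)

sim <- simulate_cohort(default_scenario(seed = 1))

# model + feature level: ET vs NC biomarkers
res <- find_biomarkers(sim$cohort, sim$atlas, "ET", "NC",
                       sl_config = searchlight_config(seed = 1),
                       perm_config = permutation_config(k = 199, seed = 1))
res$report

# statistics branch
glm <- fit_glm_tmap(sim$cohort, "ET", "NC")
cluster_report(threshold_tmap(glm, "greater"), sim$atlas)

# patient vs patient: ET vs PD, biomarkers vs whole GM
compare_direct_vs_framework(sim$cohort, res$mask,
                            eval_protocol(seed = 1))
```

## Known limitations

* The permutation stage is honest about multiplicity only to the extent the
  original framework is: no across-sub-cluster correction.
* With ~15 subjects per group, CV accuracies take coarse rational values;
  identical accuracies across sub-clusters are expected, not a bug.
* The searchlight cost is linear in mask size × folds; the R implementation
  favours clarity and determinism over raw speed and is sized for the
  synthetic grids above.
* World coordinates are reported in the volume's native affine frame; the
  synthetic atlas calls its frame "MNI-like" but no registration to any
  template is implied.
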