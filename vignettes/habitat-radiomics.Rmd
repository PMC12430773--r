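---
title: "Habitat radiomics: models, parameters, and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Habitat radiomics: models, parameters, and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: what each stage
computes, which knobs matter, what the synthetic cohort does and does not
emulate, and where genuinely open design choices were settled.

## 1. The analysis in one paragraph

Tumors are heterogeneous; single-ROI radiomics averages that heterogeneity
away. Habitat imaging partitions the tumor — and a peritumoral ring, where
the immune interface lives — into subregions ("habitats") by clustering
per-voxel multi-sequence intensity profiles, pooled over the whole cohort so
habitat indices mean the same thing in every patient. Per-habitat radiomic
features then feed a cross-validated feature-selection + classifier pipeline
to predict pathologic complete response (pCR) after neoadjuvant
chemoimmunotherapy, and linear SHAP attributions connect the selected
features back to tissue biology (PD-L1 combined positive score, immune-cell
densities).

## 2. Stages, parameters, and the reasoning behind defaults

### Preprocessing

* **Bias correction** (`correct_bias`). Smooth multiplicative inhomogeneity
  is estimated by alternating (4 iterations) a piecewise-constant tissue
  model — one level per mode of the kernel density of corrected
  log-intensities — with a polynomial surface fit (per-axis terms to fourth
  order plus pairwise second-order cross terms, on coordinates normalized to
  [-1, 1]) to the log-residual. Alternating a sharpened intensity model with
  a smooth field estimate is the principle behind N4-style correctors; the
  polynomial keeps the fit closed-form and deterministic. Density modes
  (rather than quantile bins or 1-D k-means) matter: equal-frequency bins
  necessarily cut through tissue classes and absorb the very field being
  estimated, whereas a class contributes one density mode regardless of its
  size. The estimated field is normalized to unit geometric mean and the
  output rescaled to preserve the global mean exactly. The estimator
  attenuates fields whose log-amplitude is below the separation of tissue
  modes; when bias and class gaps are comparable the decomposition is
  ambiguous for any single-channel method.
* **Resampling** (`resample_isotropic`). Target 1 mm isotropic; trilinear
  for images, nearest neighbor for masks (mask outputs stay binary). The
  output has `floor(extent / target) + 1` voxels per axis with
  `extent = (n - 1) * spacing` — stated so shape tests are exact.
  Interpolating a constant is exact to floating-point round-off (weights
  sum to 1 up to one ulp). Correction precedes resampling; registration is
  out of scope (inputs are contract-level pre-aligned, and
  `align_identity()` is the no-op hook where a registration step would go).

### Peritumoral ring (`make_peritumoral_ring`)

The ring is `{v : 0 < d(v, tumor) <= r}` with `r = 3` mm by default,
distance in physical mm honoring anisotropic spacing, the boundary closed
(`d = r` included), minus the exclusion mask (bone/air is an input mask, not
inferred). Implementation is dilation by the exact lattice ball of radius
`r`, which reproduces the distance-threshold definition exactly — the test
suite checks set equality against exhaustive distance enumeration on grids
up to 32^3, including anisotropic spacing. Voxels beyond the grid simply do
not exist (clipping, no padding).

### Habitat clustering (`fit_habitat_model`)

* Channels are z-scored over the pooled cohort matrix before K-means so no
  sequence's intensity scale dominates the Euclidean metric (this choice is
  ours; nothing in the analysis contract fixes it).
* Candidate range k = 1..10; per k, 10 k-means++ initializations refined by
  Lloyd-style iteration (cap 300), keeping the lowest-SSE restart. Seeds are
  recorded in the model. Above 2 x 10^6 pooled voxels, the elbow search
  runs on a uniform subsample (recorded seed) and the final model is refit
  on all voxels at the selected k.
* **Elbow rule**: k* maximizes the discrete second difference
  `SSE(k-1) - 2 SSE(k) + SSE(k+1)` over interior candidates; ties go to the
  smallest k (so an exactly linear curve yields k = 2). Curves that
  increase by more than 1% of their range trigger a warning (Monte-Carlo
  noise tolerance), not an error.
* **Habitat identity**: clusters are relabelled h1..hk by ascending
  centroid T1C value. Some deterministic convention is required for
  cross-run and cross-patient feature naming; contrast enhancement is the
  clinically most interpretable axis. The default phantom's class means
  have strictly increasing T1C components so this ordering is tie-free.
* Intratumoral and peritumoral regions get separate cohort-level models;
  a per-subset refit is available by pooling any patient subset.
* Degenerate input: if the pooled matrix has fewer distinct rows than k,
  each distinct value becomes a cluster (SSE 0) rather than erroring.

### Radiomic features (`extract_features`)

107 features per subregion in the standard seven classes
(14/18/24/16/16/5/14). Numerical conventions, stated because they are the
exactness surface of the tests:

* Discretization: fixed bin count 32 over the subregion's intensity range
  (scale-free across the phantom's arbitrary units); the maximum falls in
  the top bin; a constant region maps to one bin. Bin count and the
  minimum subregion size are recorded in the feature-table schema.
* First order uses raw intensities (population variance convention;
  kurtosis not excess-corrected); Entropy/Uniformity use the discretized
  histogram. A constant region has Variance = Entropy = 0 by construction.
* Texture matrices use the 13 unique 3D directions at Chebyshev distance 1.
  GLCM matrices are symmetrized and normalized per direction and feature
  values averaged over directions (directions with no voxel pairs are
  skipped); GLRLM likewise. GLSZM zones are 26-connected components per
  gray level (via graph components); GLDM dependence counts equal-gray
  26-neighbours (alpha = 0), with the dependence size including the centre
  voxel; NGTDM excludes voxels with no valid neighbour.
* Shape is voxel-based: volume = voxel count x voxel volume (the mesh-
  volume slot reports the same value), surface area by exposed-face
  counting, axis lengths from 4 x sqrt(eigenvalues) of the physical
  coordinate covariance, diameters over boundary-voxel centres (2D
  diameters via exact convex hulls; the 3D diameter prunes to
  direction-extreme points before the exact pairwise maximum). These
  differ from mesh-based estimates by design and are documented as such.
* Subregions under 10 voxels yield an all-missing vector with a recorded
  reason — texture matrices degenerate on tiny regions — and missingness is
  handled downstream by the imputer, never by dropping columns. A habitat
  index entirely absent from a cohort (possible when the two regions'
  elbows disagree) produces structurally empty columns, which the pipeline
  drops with a message before imputation.

### Modeling (`crossvalidate`, `build_model_suite`)

Per fold, fitted on the training fold only and applied unchanged to the
held-out fold: KNN imputation (NaN-aware Euclidean distances scaled by the
fraction of jointly observed columns; clinical columns use the training
median) → Z-score → Pearson redundancy filter → cross-validated LASSO →
classifier. Decisions that were genuinely open:

* **Redundancy filter victim rule**: among an offending pair (|r| > 0.95),
  drop the feature with the larger mean absolute correlation to all
  currently retained features; ties go to the lexicographically later
  name. Offending pairs are processed in decreasing |r|. Constant columns
  are removed first with a warning (undefined correlation).
* **LASSO**: gaussian objective on the 0/1 labels over glmnet's log-spaced
  penalty grid, penalty chosen by 10-fold cross-validated loss at
  `lambda.min`; inner folds are stratified so no training complement is
  single-class; when a class has a single member (impossible to
  cross-validate) the penalty falls back to BIC along the path,
  deterministically. Empty selections are allowed and flagged; the fold
  then scores at the training prevalence.
* **Selection inside vs outside CV**: default is inside each fold
  (leakage-safe); `pooled_selection` (`selection = "pooled"`) fits the selection
  once on all data before the folds are cut, mirroring the procedure many
  radiomics studies describe. Both are available because the two answer
  different questions; the leakage audit in the test suite applies to the
  default.
* **Classifiers**: logistic regression is ridge-penalized (Newton
  iterations minimizing `-loglik + ||beta||^2 / (2C)` with C = 1, intercept
  unpenalized) — well-defined even when a small training fold has one
  positive — and exposes coefficients for closed-form SHAP. SVM uses an RBF
  kernel with `plogis(decision value)` as the score (monotone in the
  decision value, so AUC is that of the margin and the 0.5 threshold is
  the SVM's own sign rule); KNN uses k = 5; decision tree and random
  forest (100 trees) run under recorded seeds. Confusion-matrix metrics
  use threshold 0.5; precision and PPV are one quantity reported twice
  because standard performance tables print both.
* Stratified folds keep each fold's class counts within one patient of
  proportionality; a fold that would contain a single class raises an
  error suggesting fewer folds. Calibration uses 10 equal-frequency bins
  of the pooled held-out predictions.

### Interpretation

For a linear model, SHAP has the closed form
`phi_ij = beta_j (x_ij - mean(background_j))` with base value equal to the
score at the background means; additivity holds to round-off and is asserted
at 1e-9. The background is the fold's training rows; attributions live on
the standardized log-odds scale. Nonlinear models are rejected with a
pointer to model-agnostic explainers (out of scope). Per-fold rankings use
mean |phi| with name-order tie-breaks; the top 3 per fold are pooled.
Associations: Welch's t (the safer default; the equal-variance choice is
not fixed by the analysis contract) between feature values dichotomized at
CPS >= 15 — the boundary value belongs to the high group — and Pearson
correlation against cell densities with |r| > 0.75 flagged strong.

## 3. What the synthetic cohort emulates — and what it does not

`generate_phantom` renders three aligned sequences on a 48 x 48 x 32 grid at
2 mm spacing (desk-scale; the pipeline resamples to 1 mm): an ellipsoidal
tumor (semi-axes 16/14/10 mm, jittered ±20% per patient) whose interior is
divided into five equal-volume concentric shells, with per-patient
boundary jitter and a smooth random warp so habitats have irregular,
contiguous borders; outside the tumor the same five classes tile the tissue
as smooth blobs, with class quantiles cut over the near-tumor band so the
peritumoral ring samples all classes in balanced proportions. Voxel
intensity = class mean + within-class Gaussian (sd 10) , multiplied by a
low-frequency bias field (product of per-axis quadratics, relative
amplitude 0.15 — the scale of residual coil inhomogeneity), plus additive
noise (sd 10). A spherical exclusion tangent to the tumor stands in for
bone/air.

The five class-mean triples are the generator's most deliberate choice.
The elbow rule is the maximum second difference of the SSE curve, and that
statistic identifies the true class count only when the SSE declines
roughly linearly up to it — i.e. when merging any two classes costs a
comparable amount of variance. Class means placed along a line or at
uneven spacings produce geometrically decaying SSE curves whose second
difference peaks at k = 2 regardless of the true k. The default means were
therefore chosen by enumerating all partitions of five points and
minimizing the coefficient of variation of the successive best-k SSE
drops, subject to strictly increasing T1C components (tie-free habitat
ordering). With that geometry the elbow selects k = 5 for both regions
robustly across seeds.

Outcome linkage: each patient's latent score is
`effect_vector . intratumoral fractions + logistic noise`, and exactly
`round(n x prevalence)` patients with the highest scores are labelled
positive — exact class counts make stratification tests exact, while
positives still shift along the effect vector. Default prevalence 0.264
reflects the clinical setting (roughly a quarter of patients reach pCR);
default effect is a strong coefficient (60) on the h2 fraction, about
three latent-scale standard deviations given the fraction variability the
shell jitter produces. Clinical covariates (induction cycles, post-
treatment T stage, albumin-globulin ratio) follow label-conditional
distributions with mild planted associations; biomarkers couple CPS to the
intratumoral h2 fraction (Poisson rate) and cell densities linearly to the
peritumoral h2 fraction, with a one-noise-sd stromal CD45+ shift in
positives.

Not emulated: MRI physics, motion, registration error, multi-scanner
effects, DICOM, realistic class overlap (the default classes are well
separated, which is why habitat recovery is near-perfect). Passing tests
therefore demonstrate algorithmic correctness and recoverability under the
stated conditions, not clinical performance — real-cohort discrimination
numbers are explicitly not reproduction targets.

## 4. Problem sizes used by the test and acceptance suites

Chosen as the package's own desk-scale working points: structural feature
counts on one phantom patient; elbow recovery on the default 20-patient
cohort (~23,000 pooled intratumoral voxels at the native grid); habitat
recovery (adjusted Rand index vs planted classes) on a low-noise 4-patient
cohort; outcome calibration on 60-patient truth-table cohorts — 20 null
seeds (mean held-out AUC should sit near 0.5) and 10 planted-effect seeds
(mean AUC should be high); ring-geometry oracles on grids up to 16^3 in
the unit suite and the stated 32^3 bound in the acceptance suite; and a
10-16 patient end-to-end imaging demo. The acceptance script
(`scripts/acceptance.R`) re-derives the feature-panel counts and the elbow
selection from scratch at these sizes.

## 5. Known limitations

* The bias corrector assumes tissue classes are separable in single-channel
  log-intensity once the field is removed; fields comparable to class gaps
  cannot be fully attributed by any single-channel histogram method.
* Voxel-based shape quantities differ from mesh-based ones (systematically
  larger surface area, slightly different diameters); comparisons across
  extractors should use one convention.
* The gaussian-objective LASSO on binary labels mirrors common radiomics
  practice but is not a likelihood-consistent logistic LASSO; it is a
  selection device, not an inference procedure.
* With ~3000 candidate features and tens of patients, cross-validated AUCs
  are noisy; the package reports per-fold spread for that reason, and the
  null-cohort behavior of the full pipeline is part of the test suite.
* The phantom's habitat spatial texture (shells plus smooth warp) is a
  convenient stand-in; it makes no claim about the spatial organization of
  real tumor ecosystems.
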