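# habitomics

Intratumoral and peritumoral **habitat radiomics** for predicting pathologic
complete response (pCR) to neoadjuvant chemoimmunotherapy from
multi-sequence MRI, with a fully synthetic phantom cohort generator so the
entire analysis is testable without patient data.

## Who this is for

Imaging scientists who want a reusable, tested R implementation of the
habitat-imaging analysis pattern: instead of treating a tumor as one
homogeneous region of interest, the tumor (and a metric ring around it) is
partitioned into *habitats* — spatially coherent subregions with similar
multi-sequence intensity profiles — and radiomic features are computed per
habitat, per sequence, per region, before feature selection and classifier
evaluation.

## The method

For each patient, three co-registered sequences (T1WI, T2WI, contrast-
enhanced T1C) are bias-corrected and resampled to isotropic voxels. The
peritumoral region is the set of voxels within 3 mm (Euclidean distance in
mm, honoring anisotropic spacing) of the tumor, minus bone/air exclusions.
Every region voxel contributes an intensity triple
`x_v = (T1_v, T2_v, T1C_v)`; triples are pooled **across the whole cohort**
into an N x 3 matrix, z-scored per channel, and clustered with K-means.
The cluster count k is chosen by the elbow of the within-cluster
sum-of-squared-errors curve, identified as the k maximizing the discrete
second difference

```
SSE(k-1) - 2 SSE(k) + SSE(k+1),   k = 2, ..., k_max - 1 .
```

Because one centroid set serves the whole cohort, habitat indices h1..hk
(ordered by ascending centroid T1C value) are comparable across patients.
Each habitat subregion then yields the standard 107-feature radiomic panel
— shape (14), first order (18), GLCM (24), GLRLM (16), GLSZM (16),
NGTDM (5), GLDM (14) — for each sequence, i.e. 1070 radiomic columns per
sequence when k = 5 in both regions, named
`{P|I}_{T1|T2|T1C}_h{n}_{Class}_{Feature}`.

Modeling follows a leakage-safe per-fold pipeline inside stratified 5-fold
cross-validation: KNN/median imputation → Z-score → Pearson redundancy
filter (|r| > 0.95) → 10-fold cross-validated LASSO → classifier (logistic
regression, SVM, KNN, decision tree, or random forest). The model suite
mirrors the usual layout: per-sequence intratumoral/peritumoral HI models,
the two fusion models, and a decision model (all habitat columns plus
clinical candidates). Linear-model SHAP attributions
(`beta_j (x_ij - mean_j)`) rank features per fold; pooled key features are
screened against PD-L1 CPS (Welch t at CPS >= 15) and immune-cell densities
(Pearson, strong when |r| > 0.75).

## Worked example

A small end-to-end run on a synthetic cohort (the default phantom plants
five latent tissue classes and links the outcome to intratumoral habitat
composition):

```r
library(habitomics)

cfg <- pipeline_config(
  out_dir = tempfile("demo_"),
  cohort = cohort_config(n_patients = 16, prevalence = 0.25, seed = 42),
  target_spacing_mm = 2, cv_folds = 4,
  models = c("T1C-Intra", "Intra-Fusion", "Peri-Fusion", "Decision"),
  seed = 7
)
bundle <- run_pipeline(cfg)
glance(bundle$habitat_models$intratumoral)
#> # A tibble: 1 x 6
#>   region       k_selected k_min k_max n_voxels      seed
#> 1 intratumoral          5     1    10    19248 681981686
```

The elbow recovers the five planted classes from the 19,248 pooled
intratumoral voxels. `bundle$suite$report` holds the per-model mean
held-out metrics; at 16 patients the radiomic models are honestly noisy
(AUCs of roughly 0.4-0.8 across scopes in this run), which is the expected
behavior of a 3210-column radiomics model on a 16-patient cohort.
Discrimination is better assessed on the tabular layer at a larger n,
where the generator's planted log-odds effect on habitat h2 is recovered
cleanly:

```r
co <- generate_cohort(cohort_config(n_patients = 60, prevalence = 0.264,
                                    effect_vector = c(0, 60, 0, 0, 0),
                                    seed = 11),
                      render = FALSE)
feats <- co$table[, c(grep("_frac_h", names(co$table), value = TRUE),
                      "induction_cycles", "post_t", "agr")]
cv <- crossvalidate(feats, co$table$label, classifier = "lr",
                    n_folds = 5, seed = 11,
                    clinical_cols = c("induction_cycles", "post_t", "agr"))
glance(cv)
#> # A tibble: 1 x 11
#>   classifier n_folds selection   auc accuracy recall precision    f1   ppv   npv
#> 1 lr               5 fold      0.954    0.884  0.683     0.875 0.852 0.875 0.906
```

The mean held-out AUC of 0.954 shows the planted effect is recoverable;
with `effect_vector = rep(0, 5)` the same pipeline averages near 0.5
(chance), which the test suite checks over 20 cohort seeds.

`autoplot()` methods exist for habitat models (SSE elbow curve),
cross-validation results (per-fold ROC), and SHAP explanations (global
importance); `tidy()`/`glance()` return per-fold and one-row summaries.

## Limitations

The phantom emulates aligned sequences, smooth multiplicative bias, and
spatially coherent tissue classes — not MRI physics, registration error, or
scanner heterogeneity. Passing recovery tests on phantoms demonstrates the
pipeline's correctness, not clinical performance; see the methods vignette
(`vignettes/habitat-radiomics.Rmd`) for the full account of assumptions,
parameter choices, and known limitations.
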