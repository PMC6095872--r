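# radiomix

Multi-modality tumor radiomics in R: from PET/DCE-MRI voxels to cluster
phenotypes and outcome prediction.

## What problem this package addresses

Radiomics turns medical images into quantitative tumor descriptors and asks
whether those descriptors carry phenotypic or prognostic information. This
package implements that analysis for paired PET and dynamic contrast-enhanced
MR images of tumors with expert-delineated masks, for researchers who want a
tested, reproducible pipeline rather than a pile of scripts:

1. **Preprocessing** — isotropic resampling (trilinear images,
   nearest-neighbor masks; defaults 2.0 mm PET / 0.5 mm MR) and SUV
   conversion
   `SUV = C · weight / (dose · 2^(−Δt/T½))`.
2. **Feature extraction** — 42 features per modality, 84 per tumor:
   9 first-order intensity statistics, 8 three-dimensional shape descriptors
   (with an exact face-count and a convergent mesh surface-area estimator),
   and 25 gray-level co-occurrence matrix (GLCM) texture features computed on
   fixed-bin-width discretized intensities (0.1 SUV / 5.0 a.u.) and averaged
   over the 13 unique voxel directions at distance 1.
3. **Consensus clustering** — subsampled co-clustering over a menu of
   algorithms (Ward HC, k-means, k-means on distances, PAM) × dissimilarities
   (1−Pearson, 1−Spearman, Euclidean); the cluster number maximizes the
   relative change Δ(k) in the area under the consensus CDF, and the
   algorithm most associated with a clinical variable is chosen by Cramér's
   V.
4. **Association statistics** — χ² / Cramér's V for cluster–outcome tables,
   Spearman ρ for ordered outcomes, and the proportion of variance explained
   `r²_mreg = SS_between / SS_total` for unordered outcomes.
5. **Classification** — repeated stratified nested cross-validation (3-fold
   inner/outer) of dichotomized recurrence-free survival (1–5-year cutoffs)
   and tumor grade (1–2 vs 3–4) over regularized logistic regression
   (L1/L2/ElasticNet), SVM and random forest, with bootstrap AUC confidence
   intervals and coefficient-stability feature tallies.
6. **Synthetic cohorts** — a generator of textured ellipsoidal PET/MR tumors
   whose clinical outcomes are coupled to known latent groups, so the entire
   pipeline is testable without patient data.

Everything is tibble-first and pipe-friendly; fitted objects support
`tidy()`, `glance()` and `autoplot()`.

## Worked example

```r
library(radiomix)

# 1. a reproducible synthetic cohort (3 latent tumor groups, n = 30)
cohort <- generate_cohort(cohort_spec(seed = 42, n_tumors = 30))

# 2. preprocess + extract 84 radiomic features per tumor
features <- extract_cohort_features(cohort$manifest, mr_spacing = 1.0)

# 3. consensus clustering of the z-scored feature table
scaled <- zscore_table(features)
run <- run_consensus(scaled, algorithm = "HC", dissimilarity = "pearson",
                     k_range = 2:5, n_iter = 500, seed = 1)
tidy(run)
#> # A tibble: 4 × 4
#>       k     A  delta median_cc
#>   <int> <dbl>  <dbl>     <dbl>
#> 1     2 0.465 0.465      0.982
#> 2     3 0.690 0.484      1
#> 3     4 0.744 0.0785     1
#> 4     5 0.788 0.0600     0.992
```

Δ(k) peaks at k = 3: the consensus CDF area jumps when the resampled
partitions lock onto the three planted groups and barely improves beyond.
The labels recover the planted groups exactly, and the clusters associate
with the (group-coupled) tumor grade:

```r
k <- select_num_clusters(run)                               # 3
median_cluster_consensus(run, k)                            # 1
label_agreement(run$labels[[as.character(k)]],
                cohort$truth$group)                         # 1  (adjusted Rand)

cramers_v_test(run$labels[[as.character(k)]], cohort$clinical$grade)
#> # A tibble: 1 × 5
#>    chi2        p   dof cramers_v     n
#>   <dbl>    <dbl> <int>     <dbl> <int>
#> 1  22.4 0.000163     4     0.612    30
```

Nested cross-validated classification of dichotomized grade, with the
stability tally of which features carried nonzero ElasticNet coefficients:

```r
grade <- dichotomize_outcomes(cohort$clinical, "grade")
X <- features[match(grade$tumor_id, features$tumor_id), ]
cv <- nested_cv_auc(X, grade$label, classifier_spec("logistic", "ElasticNet"),
                    reps = 25, seed = 7)
glance(cv)
#> # A tibble: 1 × 8
#>   classifier        mean_auc ci_lo ci_hi n_fits  reps outer_folds  seed
#>   <chr>                <dbl> <dbl> <dbl>  <dbl> <dbl>       <int> <dbl>
#> 1 elasticnet_logreg    0.952 0.940 0.963     75    25           3     7

head(cv$top_features, 5)
#> # A tibble: 5 × 3
#>   feature                 count proportion
#>   <chr>                   <int>      <dbl>
#> 1 PET_contrast               75      1
#> 2 PET_difference_variance    75      1
#> 3 MR_imc1                    71      0.947
#> 4 PET_difference_average     71      0.947
#> 5 PET_dissimilarity          71      0.947
```

The mean AUC of 0.95 reflects the strong planted grade–group coupling of this
synthetic cohort; the texture features that differ most between the planted
groups top the tally. (glmnet may warn about convergence at the weakest grid
penalties; the path solutions are still returned.)

`run_pipeline(pipeline_config(...))` chains all stages and writes
features/cluster/association/CV artifacts plus a JSON report to a directory.
`vignettes/radiomics-methods.Rmd` documents the models, conventions and
design choices in detail.

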