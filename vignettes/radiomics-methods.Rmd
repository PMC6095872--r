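---
title: "Methods: multi-modality tumor radiomics from feature extraction to outcome models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-modality tumor radiomics from feature extraction to outcome models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

radiomix implements a complete PET + DCE-MRI radiomics analysis: per-tumor
feature extraction, unsupervised consensus clustering of the cohort,
association statistics against clinical outcomes, and repeated nested
cross-validated classification of recurrence-free survival (RFS) and tumor
grade. This vignette is the package's own account of the methods: the models
and their assumptions, the parameters that matter, the numerical conventions,
and what the synthetic validation cohort does and does not establish.

```{r setup, eval = FALSE}
library(radiomix)
```

## Imaging model and preprocessing

A tumor is represented by an `image3d` (scalar voxel grid, per-axis spacing
in mm, modality, intensity units) and an aligned binary `mask3d`. The mask is
an *input*: tumor segmentation is out of scope, and the pipeline assumes the
region was delineated and reviewed upstream.

**Isotropic resampling.** PET and MR grids arrive with different, usually
anisotropic spacings, so all volumes are resampled to isotropic voxels before
feature extraction: 2.0 mm for PET and 0.5 mm for MR by default, both
overridable. Images are interpolated trilinearly; masks use nearest-neighbor
so they remain binary (fractional membership would poison the co-occurrence
counts). Image and mask are resampled jointly onto the same grid — whether
masks should be drawn before or after resampling is genuinely open, and
resampling them jointly is the only choice that keeps the pair aligned.
Output voxel centers start at the first input voxel center and never
extrapolate beyond the input extent.

**SUV conversion.** PET voxels in activity concentration \(C\) (kBq/ml) are
converted to standardized uptake values

\[ \mathrm{SUV}(v) \;=\; \frac{C(v)\, \cdot\, \text{weight}_{\mathrm g}}
   {\text{dose}_{\mathrm{kBq}} \cdot 2^{-\Delta t / T_{1/2}}} , \]

with the injected dose decayed over the injection-to-scan delay \(\Delta t\).
The half-life defaults to 109.77 min (fluorine-18) and is configurable; a
caller holding an already decay-corrected dose passes a delay of 0. MR
intensities are used as-is in arbitrary units (no cross-scanner
harmonization), matching direct use of the first post-contrast frame.

**Discretization.** First-order histogram statistics and all texture features
operate on gray levels obtained with a *fixed bin width* rather than a fixed
bin count: level \(= \lfloor (I - I_{\min})/w \rfloor + 1\) inside the mask,
0 outside, with \(w = 0.1\) SUV for PET and \(w = 5.0\) units for MR by
default. The first bin is anchored at the masked minimum and the masked
maximum falls in its ordinary floor bin (no special edge bin); a constant
region is valid and produces a single level. Fixed-width binning keeps level
differences comparable across tumors, which matters because several texture
features are functions of \(|i-j|\).

## The 42 radiomic features

Each image–mask pair yields 9 first-order, 8 shape and 25 GLCM texture
features; a PET+MR tumor therefore contributes 84 columns (`PET_*`, `MR_*`).
The names are frozen in `feature_registry()` so downstream importance tallies
are stable.

**First-order (9).** min, max, mean, variance, skewness, kurtosis, histogram
entropy \(-\sum_h p_h \log_2 p_h\), energy \(\sum_v I(v)^2\), and histogram
uniformity \(\sum_h p_h^2\). Conventions worth stating: variance and the
moment ratios use population moments (divisor \(n\)); kurtosis is the plain
moment ratio \(m_4/m_2^2\) (not excess); a zero-variance region returns
skewness and kurtosis 0 rather than NaN. "Energy" is ambiguous in the
radiomics literature — here it is the sum of squared voxel intensities (the
common first-order definition), while the *histogram* statistics entropy and
uniformity use the fixed-bin-width histogram.

**Shape (8).** Volume \(V\) (voxel count × voxel volume), surface area
\(A\), surface-to-volume ratio, compactness1 \(V/(\sqrt{\pi}A^{3/2})\),
compactness2 \(36\pi V^2/A^3\), sphericity \(\pi^{1/3}(6V)^{2/3}/A\),
spherical disproportion \(A/(4\pi R^2)\) with \(R=(3V/4\pi)^{1/3}\), and the
maximum 3-D diameter (largest pairwise Euclidean distance between
surface-voxel centers). Two surface estimators are provided because no single
one is right for both test geometries and real tumors:

* `face_count` sums exposed voxel faces. It is exact on axis-aligned boxes
  (the cube unit tests rely on that) but does **not** converge to the true
  area of curved surfaces — a digitized ball keeps a staircase surface at any
  resolution, inflating \(A\) by up to ~50%.
* `mesh` (the default) triangulates the 0.5-isosurface of a lightly smoothed
  copy of the mask (Gaussian, \(\sigma = 0.8\) voxel) by marching tetrahedra
  with linear edge interpolation. The presmoothing is essential: meshing the
  raw binary volume reproduces the staircase and overestimates a ball's area
  by 8–27% depending on the triangulation, while the smoothed isosurface
  tracks the underlying smooth shape. A pre-build convergence check on
  digitized balls measured sphericity 1.012 (radius 8 voxels), 0.999
  (radius 12) and 0.992 (radius 20) against the ideal 1.0, which sets the
  0.03 tolerance used in the shape tests. The trade-off is deliberate:
  \(\sigma\) large enough to suppress voxelization, small enough not to
  erode real morphology; 0.8 voxels sits at that balance and is not exposed
  as a user knob.

**GLCM texture (25).** The gray-level co-occurrence matrix for displacement
\(\mathbf d\) counts masked voxel pairs at \(\pm\mathbf d\) (symmetric
accumulation) and normalizes to probabilities \(p(i,j)\). In 3-D the
26-neighborhood at distance 1 contains 13 unique direction representatives
(`glcm_offsets()`); one matrix is built per direction and each feature is
reported as the mean over the directions that contain at least one valid
pair. The 25 features are autocorrelation, cluster prominence/shade/tendency,
contrast, correlation, difference average/entropy/variance, average intensity
(\(\mu_x\)), dissimilarity, energy, entropy, homogeneity1/2, IDMN, IDN,
inverse variance, maximum probability, sum average/entropy/variance, sum of
squares, and IMC1/IMC2. Conventions:

* Logarithms are base 2 and \(0\log 0 := 0\).
* Sum variance is computed about the **sum average**
  (\(\sum_k (k-\mathrm{SA})^2 p_{x+y}(k)\)), not about the sum entropy as in
  Haralick's original table — the latter is widely regarded as a typo, and
  the chosen form matches the "spread about the GLCM average" reading and
  the modern reference implementations.
* Inverse variance sums over \(i \neq j\) only; for a single-level region it
  is 0.
* IDMN and IDN normalize by the per-image observed gray-level count
  \(N_g\) (no global cap), consistent with per-tumor discretization.
* Degenerate constant regions must not produce NaN: correlation is defined
  as 1 when \(\sigma_x = 0\), and IMC1/IMC2 are 0 when \(H_X = H_Y = 0\).
* The direction set is closed under axis permutation, so direction-averaged
  features are invariant to permuting the grid axes (tested), and every
  feature matches a brute-force pair-enumeration oracle to \(10^{-10}\)
  (tested on random grids).

## Consensus clustering

Cohort structure is explored by consensus clustering of the z-scored
84-feature table. Each of `n_iter` iterations draws a subsample of items
without replacement (fraction 0.8 by default — the customary choice for this
resampling scheme; the subsample is shared across all candidate \(k\)),
clusters it, and accumulates, for every item pair, how often the pair was
clustered together relative to how often it was co-sampled. That ratio is the
consensus matrix \(M_k(i,j) \in [0,1]\).

The algorithm menu is hierarchical clustering with Ward linkage (`HC`),
k-means on the data matrix (`KM`, Euclidean geometry only), k-means on the
rows of the dissimilarity matrix (`KMdist`), and partitioning around medoids
(`PAM`), each combined with 1−Pearson, 1−Spearman or Euclidean
dissimilarity between item feature profiles (constant profiles are guarded to
correlation 0). Final labels at each \(k\) come from average-linkage
hierarchical clustering of \(1 - M_k\), the convention of the resampling
scheme's reference implementation; the choice matters little when consensus
is crisp and is stated here because it is not forced by the method.

**Choosing \(k\).** Let \(A(k)\) be the area under the empirical CDF of the
upper-triangle entries of \(M_k\) (integrated over \([0,1]\)). Concentrated
consensus (entries near 0 and 1) raises \(A(k)\). The selected \(k\)
maximizes the relative change \(\Delta(k) = (A(k)-A(k-1))/A(k-1)\), with
\(\Delta(k_{\min}) = A(k_{\min})\); ties break toward smaller \(k\)
(parsimony). **Cluster quality** is summarized by the median over clusters of
the mean within-cluster consensus (singletons count 1). **Algorithm
selection** against a clinical variable uses Cramér's V between the run's
labels at its selected \(k\) and the variable, highest V winning, ties to run
order.

The default is 10,000 iterations; the iteration count is an explicit knob and
the test suite runs 100–500 iterations, which is
already enough for the consensus entries of a well-separated cohort to
stabilize (the planted-recovery tests pass at 500 across 20 resampling
seeds). An item pair never co-sampled is imputed 0 with a warning — at
realistic iteration counts this cannot happen.

## Association statistics

* **Cluster vs. categorical outcome:** \(\chi^2\) test of independence on the
  contingency table, *without* continuity correction (tables are general
  \(r \times c\)), with Cramér's
  \(V = \sqrt{\chi^2 / (n(\min(r,c)-1))}\). Significance level 0.05.
* **Feature vs. ordered outcome:** Spearman's \(\rho\) with midrank ties,
  pairwise-complete. The full matrix is always written; \(|\rho| > 0.2\) is a
  *display* threshold only.
* **Feature vs. unordered outcome:** proportion of variance explained by the
  dummy-coded outcome, \(r^2_{mreg} = SS_{between}/SS_{total}\) (one-way
  ANOVA \(\eta^2\), identical to the \(R^2\) of the dummy-coded
  least-squares fit — the equivalence is tested against `lm()`);
  \(r^2_{mreg} > 0.04\) is again only a display filter. Zero total variance
  returns 0 with a warning.
* **Z-scoring** uses the population SD (divisor \(n\)); the scaling
  parameters are returned so held-out rows can be transformed with training
  statistics exactly. Constant columns are flagged, left untouched and
  warned about. Missing clinical values are excluded pairwise, so each
  outcome has its own effective \(n\).

No multiple-testing correction is applied — the association tables are
exploratory screens, not confirmatory inference.

## Classification of RFS and tumor grade

Outcomes are dichotomized first: grade 1–2 → 0 vs. grade 3–4 → 1; for RFS at
cutoff \(y \in \{1,\dots,5\}\) years, recurrence-free beyond \(y\) → 1, and
everyone else — recurrence at or before \(y\), or never disease free — → 0.
Rows with missing outcomes are excluded and counted.

`nested_cv_auc()` runs repeated stratified nested cross-validation with
3-fold inner and outer splits. Per outer-train fold: features are z-scaled
with that fold's own mean/SD (never the full data's — z-scaling the full
table once before splitting would leak held-out statistics into training, so
the scaler lives inside the loop), hyperparameters are chosen by
inner-CV mean AUC, the winner is refit on the outer-train fold and scored on
the held-out fold by rank-based (midrank/trapezoidal) AUC. All
`reps × 3` outer-fold AUCs are retained; their mean and a percentile 95% CI
from 1000 bootstrap resamples *of the AUC list* (resampling patients is the
other defensible choice; the AUC list was chosen and is stated here) are
reported.

The classifier menu is regularized logistic regression (L1, L2, ElasticNet
via glmnet), an RBF SVM, and a random forest. Hyperparameter grids are not
dictated by the method, so the defaults are explicit and recorded in every
result: inverse-regularization strengths \(C \in \{0.01, 0.1, 1, 10\}\)
(mapped to the glmnet penalty as \(\lambda = 1/(nC)\)), ElasticNet mixing
\(\alpha \in \{0.2, 0.5, 0.8\}\), 100 trees, SVM \(C\) grid with the "scale"
gamma. Inner-CV ties resolve toward the stronger penalty.

**Feature importance** is a stability tally, not a coefficient magnitude: for
each of the `reps × 3` outer fits, a feature counts as selected when its
fitted coefficient is nonzero (L1/ElasticNet) or exceeds 0.01 in absolute
value (L2, where nothing is exactly zero). Proportions are reported against
the maximum number of CV fits and the top 10 are ranked, ties alphabetical.
`reps` defaults to
1000, which makes the tally denominator 3000 = 1000 × 3 outer folds; smaller
values are appropriate for exploration and are used throughout the test
suite. Non-coefficient
models (SVM, random forest) carry no tally and `plot_feature_importance()`
refuses them rather than inventing a surrogate.

## The synthetic cohort: what it emulates and what it does not

Real PET/MR cohorts of this kind are not publicly shareable, so the package
ships a generator whose defaults define its reference validation cohort: 90
tumors in three equal latent groups. Tumors are ellipsoids (per-group
semi-axes with ±15% jitter) rasterized at 2.0 mm (PET) and 1.0 mm (MR);
interior intensity is the group mean plus a unit-variance Gaussian random
field — white noise smoothed at the group's correlation length, an
interpretable texture knob — mixed with 30% white noise. PET fields are
stored in activity units chosen so that SUV conversion with the manifest's
weight/dose/delay reproduces the intended SUV scale, exercising the real
preprocessing path.

The three groups deliberately differ in *complementary* directions — low
uptake/strong MR enhancement/fine texture; high uptake/weak enhancement;
intermediate intensities/coarse texture/larger size — so that no two groups
are systematically closer to each other than to the third. An earlier design
with groups ordered along a single intensity axis made two groups merge
stably, which is a property of that geometry rather than of the clustering
machinery; the complementary design is the intended planted-partition
condition and is frozen as the default.

Clinical outcomes are coupled to the latent groups: grade and subtype from
per-group categorical tables, stages from volume-tertile tables, and
recurrence from a logistic model on standardized true mean SUV and log
volume (intercept −1.7, slopes 1.0 and 0.5, ~8% "never disease free"),
yielding roughly 70/20/10 no-recurrence/recur/never-free splits. Everything
is reproducible from `(spec, seed)`, and the truth record (groups, true
parameters) suffices for recovery metrics without regeneration.

What the generator does **not** emulate: scanner physics (PSF, noise
correlations, partial-volume effects), DCE kinetics, non-ellipsoidal
morphology, segmentation error, missing clinical data patterns, or the
feature-covariance structure of real tumors. Passing the recovery tests
therefore demonstrates that the pipeline's machinery is correct and
well-calibrated — that planted structure of a stated effect size is found,
that null data yields AUC 0.5, that counts and guards behave — not that any
particular clinical effect size is attainable on real images.

**Problem sizes.** The validation suite runs the reference cohort (n = 90,
MR at 1.0 mm) with 500-iteration consensus runs over 20 resampling seeds,
the CV-harness check at 1000 repetitions × 3 folds = 3000 fits on a 60 × 9
table, and null calibration at 50 repetitions — sizes chosen so the whole
suite completes on a desk machine while still exercising every code path at
the reference repetition counts where it matters (the 3000-fit tally).

## Numerical conventions and edge cases

* All stochastic functions take an explicit integer seed and restore the RNG
  state afterwards; identical seeds give byte-identical results end to end.
* Constant image regions: valid everywhere (single gray level, single-entry
  GLCM, guards above); disconnected masks with no voxel pairs in any
  direction are an error naming the cause.
* Empty mask after resampling is an error naming the tumor.
* A missing modality in a cohort manifest yields NA feature columns and a
  warning, not a dropped row, so tumor identity is preserved downstream.
* Cluster-number ties go to smaller k; inner-CV ties to the stronger
  penalty; importance ties are alphabetical. All three are stated because
  they silently shape results otherwise.

## Known limitations

* The mesh surface estimator is tuned for tumor-like blobs a few voxels
  across or larger; for masks 1–2 voxels thick the presmoothing can merge or
  erode structure, and `face_count` is the honest choice there.
* GLCM features are the only texture family implemented (by design — the
  package keeps a compact 84-feature set rather than the 900+ features of
  size-zone/run-length/wavelet families);
  size-zone, run-length and wavelet features are out of scope.
* `KM` with correlation dissimilarities is refused rather than silently
  reinterpreted, since k-means optimizes Euclidean geometry on the data
  matrix.
* The SVM and random-forest menu entries produce AUCs but no importance
  tallies; permutation importance is deliberately not implemented.
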