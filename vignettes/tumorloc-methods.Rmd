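---
title: "Tumor location features and survival prediction: methods"
author: "TumorLoc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tumor location features and survival prediction: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TumorLoc)
```

## The problem

Glioblastoma is the most aggressive primary brain tumor; overall survival
(OS) after diagnosis varies from days to years, and predicting it from
pre-operative MRI is hard. Wide radiomic panels (thousands of intensity,
shape and texture descriptors per patient) tend to overfit small cohorts.
This package implements and evaluates a complementary idea: four cheap
*location* features of the tumor — where it sits in the brain and how big
it is — carry survival signal of their own, and adding them to a reduced
radiomic panel improves classification of short versus long survivors.
Cohorts are analysed separately by resection status (gross total
resection, GTR, versus unreported, NA), because surgical extent
confounds any image-based predictor.

## Location features

The segmentation volume follows the BraTS label convention (0 background,
1 necrotic core, 2 edema, 4 enhancing tumor); the tumor mask is the union
of a configurable label set, whole tumor {1, 2, 4} by default. For every
axial slice the in-plane tumor diameter is the maximum pairwise Euclidean
distance between in-mask voxel centers, scaled to mm. Then:

* **Slice** — the axial index with the largest diameter (the tumor's
  middle surface). Ties go to the smaller index, for determinism.
* **Diameter** — that maximal diameter, in mm.
* **X**, **Y** — signed longitudinal and transverse offsets (mm) of the
  tumor-mask centroid from the brain-mask centroid on the selected slice,
  positive toward increasing array index.

The diameter is computed from the convex hull of the scaled in-mask
points followed by all-pairs search over hull vertices; this is *exactly*
the brute-force all-pairs maximum (the farthest pair of a finite point
set are both hull vertices), and the test suite asserts exact equality
against an O(n^2) oracle on hundreds of random masks. Neither the "center
of the tumor" nor the brain's "midline crossing" has a canonical
definition; we adopt mask centroids because they are deterministic and
orientation-free, and offer the bounding-box midpoint of the brain mask
(`center = "midline"`) as an alternative. The slice axis is the third
array axis; whatever slice count the volume has is iterated.

## Preprocessing

Intensities are z-score normalized, $z = (x - \mu)/\sigma$, with the
*population* (divide-by-N) standard deviation, so that the normalized
in-scope mean is exactly 0 and the SD exactly 1. Statistics are computed
over the brain mask (nonzero voxels) by default rather than the whole
grid — background air would otherwise dominate $\mu$ and $\sigma$ — with
a switch for whole-image statistics. Low-frequency bias-field removal is
delegated to the established N4 algorithm through an external SimpleITK
backend; re-deriving N4 is out of scope, and a passthrough backend exists
for already-corrected data (it warns, and a missing external backend is
an error, never a silent fallback). Bias correction is applied before
normalization when both are requested.

## The reduction cascade

Radiomic-style tables are wide (features far outnumber patients), so the
pipeline prunes them in a fixed order; each stage consumes the previous
stage's output:

1. **Standardization** to mean 0, population SD 1 per feature (constant
   features are dropped and reported).
2. **Correlation pruning** at $|r| > 0.95$: feature pairs above the
   threshold form a graph; each connected component keeps exactly its
   highest-variance member. Variability is judged on
   *pre-standardization* variances, passed explicitly — after
   standardization all variances are 1 and "keep the most variable" would
   be vacuous. Components are the transitive closure of the relation, so
   a survivor may still correlate above threshold with a *pruned*
   feature, but no above-threshold pair both survive.
3. **VIF pruning** at 10: the variance inflation factor of feature $j$ is
   $1/(1 - R_j^2)$ with $R_j^2$ from regressing $j$ on all other
   features. While any VIF exceeds 10 the worst feature is removed and
   all VIFs recomputed; the final maximum is re-verified, not assumed.
   $R^2$ uses rank-aware least squares (QR), so perfectly collinear and
   wider-than-tall designs are handled ($R^2 \ge 1 - 10^{-12}$ counts as
   infinite VIF); when the correlation matrix is comfortably invertible
   the whole VIF vector comes from its inverse diagonal, which is the
   same quantity computed faster.
4. **PCA** on the standardized survivors: keep the smallest number of
   components whose cumulative explained-variance ratio (eigenvalue over
   trace) reaches 95%.
5. **Univariate selection**: per feature, the two-sided p-value of the
   slope t-test of survival days on that feature; the
   Benjamini–Hochberg step-up rule at $\alpha = 0.05$ picks the final
   subset. Both the VIF-selected features and their principal components
   are filtered this way, giving two parallel subsets for the
   classifiers. BH is implemented from its step-up definition and is
   cross-checked in the tests against both a literal oracle and the
   adjusted-p route.

Ties anywhere (equal variance, equal VIF, BH boundary) resolve to the
earliest column index.

## Prediction models and evaluation

Survival is dichotomized at 450 days; the boundary day itself is "long"
(the class definitions "< 450" / "> 450" leave 450 unassigned, so a
convention is required). Regression models fit the exact survival days.

The evaluation protocol is seeded, stratified 5-fold cross-validation
with pooled out-of-fold predictions — small strata (~100 patients) make
a single hold-out split unstable. Univariate regressors (linear
regression; random forest, 100 trees; radial-kernel support vector
regression with unit kernel scale) are scored by Spearman R, MSE, median
and mean absolute error between pooled out-of-fold predictions and
observed days, plus the two-sided p of the Spearman test, defined
uniformly for all three models since forests and SVR have no native
slope test. One caveat is documented deliberately: pooled out-of-fold
predictions share fold-level structure with the outcomes (each fold's
training mean anti-correlates with its held-out mean), which makes this
p-value mildly anti-conservative under the null; the calibrated
quantities are the slope tests of the reduction stage, and the unit tests
assert exactly the properties that do hold.

Classifiers (single-hidden-layer neural network; random forest, 100
trees; k-nearest neighbours, k = 5) are scored by pooling out-of-fold
predicted classes into one confusion matrix: accuracy, precision,
sensitivity, specificity, with "short" survival as the positive class
(the clinically alarming one; no convention is stated in the field's
tables). A ratio with zero denominator is NaN and flagged, never
silently 0. The network has 16 logistic hidden units, a logistic output
and is trained on the binary cross-entropy for at most 1000 iterations
with seeded initial weights; logistic rather than rectified units because
the installed single-hidden-layer implementation (`nnet`) offers exactly
this architecture with the right loss, and at 16 units the activation
choice is immaterial to the study's question. Hyperparameters live in
`pipelineConfig()` so every run is reproducible and overridable.

The cohort check uses the classical one-way fixed-effects ANOVA F test
(`anovaPvalue`) to confirm that age and survival do not differ
significantly between resection strata before models are trained
separately on them.

## The synthetic study

Real BraTS data are registration-gated, so the package ships a generator
that emulates the relevant structure with known ground truth:

* **Phantoms** (`makeLabeledVolume`): concentric ellipsoidal shells
  (core, enhancing, edema) voxelized by the closed inequality
  $\sum_a ((x_a - c_a)/(f r_a))^2 \le 1$ on voxel centers, boundary
  inside, for determinism. The ground-truth record carries the analytic
  center, per-slice analytic diameter and maximal slice. The default grid
  is 64 x 64 x 48 voxels (full 240 x 240 x 155 BraTS geometry is a
  parameter away) — small enough that a 100-patient study generates in
  ~2 s.
* **Intensities** (`makeIntensityVolume`): tissue means times a smooth
  multiplicative bias field (exponential of a separable quadratic, the
  simplest smooth field, with a set maximum log-amplitude) plus Gaussian
  noise.
* **Feature tables** (`makeFeatureTable`): blocks sharing one latent
  factor, $x = \sqrt{\rho} z + \sqrt{1-\rho}\,\varepsilon$, so
  within-block correlation is exactly $\rho$ in population; plus
  independent noise features. This reproduces the redundancy that makes
  correlation and VIF pruning necessary.
* **Cohorts** (`makeCohort`): survival days
  $\mathrm{round}(\mathrm{clip}(\beta_0 + \sum_i \beta_i f_i +
  \varepsilon))$ clipped to [3, 1767] days — the observed OS range of
  the BraTS 2019 glioblastoma training cohort — with GTR/NA assigned at
  a split fraction. The bundled study (`makeSyntheticStudy`) uses
  $\mathrm{days} = 400 - 15\,Y + \varepsilon$, $\varepsilon \sim
  N(0, 100^2)$: all survival signal lives in the transverse offset Y and
  none in the radiomic-style features, so any accuracy gained by adding
  location features is attributable to them by construction.

What the generator does *not* emulate: real MRI texture, lesion
irregularity, registration error, multifocal tumors, or any true
radiomics–survival association. Passing tests therefore demonstrate that
the machinery is correct and that it recovers signal that is present —
not that location features predict survival in real patients, which
requires the gated cohort.

One voxelization subtlety is worth recording. For an ellipsoid with
fractional semi-axes, the in-plane radius shrinks only second-order near
the center slice (~0.04 voxel per slice at typical sizes), so adjacent
slices often tie *exactly* in voxelized diameter and the smallest-index
tie-break selects the slice below the analytic center. Recovery tests
therefore use phantoms with whole-voxel semi-axes, where the center
slice is strictly maximal and the ground truth is unambiguous at voxel
resolution; this is a property of voxelization, not of the extractor.

## Problem sizes and tolerances

The shipped verification uses: 5 synthetic volumes for the normalization
contract (1e-9); 200 random masks for exact diameter-oracle equality;
50 phantom geometries for location recovery (half a voxel); a 200 x 300
collinear table for the reduction postconditions; 1000 random p-vectors
plus a 500-replicate simulation with 90% null features for BH
correctness and FDR control; 100 seeded cohorts of 120 patients for the
univariate survival signal and 20 seeded cohorts of 100 for the
classifier comparison; 500 replicates each for the ANOVA and slope-test
null calibrations (0.05 +/- 0.02). These sizes keep the whole suite
within a few minutes while leaving Monte-Carlo error well below every
asserted margin.

## Known limitations

* The diameter is 2D (in-plane); a 3D maximal Feret diameter is a
  different feature and out of scope.
* The anatomical midline is approximated by mask centroid or bounding-box
  midpoint; atlas registration would be needed for a true midline.
* The pooled-CV Spearman p-value is anti-conservative under the null, as
  discussed above.
* Resection strata are processed fully independently, including
  standardization statistics; no information is shared between them.
* Survival is treated as a plain number or a binary class; censoring and
  survival-specific models (Cox, parametric) are out of scope.
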