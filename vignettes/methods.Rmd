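---
title: "Methods: radiomics classification of craniopharyngioma subtype and mutation status"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: radiomics classification of craniopharyngioma subtype and mutation status}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Craniopharyngiomas come in two histological subtypes — adamantinomatous
(ACP) and papillary (PCP) — that carry largely subtype-specific, mutually
exclusive driver mutations: BRAF V600E in papillary tumors and CTNNB1
(β-catenin) exon-3 mutations in adamantinomatous tumors. Because targeted
BRAF/MEK therapy is an option for BRAF-mutant tumors, a noninvasive,
image-based prediction of subtype and mutation status before surgery is
clinically valuable. `cpradiomics` implements a complete radiomics pipeline
for this problem: high-throughput feature extraction from a segmented T1
tumor volume, segmentation-robustness screening, random-forest feature
selection, cross-validated vote-score evaluation, and nomogram reporting —
together with a seeded synthetic-cohort generator so that every stage is
testable without patient data.

## Feature bank (1021 features per case)

* **Location (464).** The tumor centroid (intensity-unweighted, in mm) is
  compared against the centers of 116 atlas regions: for each region the
  signed displacement `(dx, dy, dz) = tumor − center` and its Euclidean
  norm, in atlas row order. Spatial normalization itself (registration to a
  common space) is an external preprocessing step; the package consumes an
  already-normalized atlas-center table (TSV: label, x_mm, y_mm, z_mm) and
  its tests use a synthetic one.
* **Clinical (2).** Gender (male = 1) and age in years.
* **Intensity (21).** First-order statistics of the in-mask intensities.
  Moments use the population (n) denominator; kurtosis is Pearson
  (non-excess); entropy and uniformity are computed on the discretization
  histogram; `total_energy` multiplies the sum of squares by the voxel
  volume. Zero-variance ROIs return skewness/kurtosis 0 with a warning
  rather than NaN.
* **Shape (15).** Volume by voxel counting; triangulated surface area (see
  *Numerical choices*); the compactness/sphericity family; maximum 3D and
  per-plane 2D diameters over surface voxels; principal-axis lengths
  `4 * sqrt(eigenvalue)` of the voxel-cloud second moments; elongation
  `sqrt(minor/major eigenvalue)`.
* **Texture (39).** 16 GLCM features from symmetric, margin-normalized
  co-occurrence matrices at distance 1, computed per direction over the 13
  unique 3D offsets and averaged over directions with at least one pair;
  13 GLRLM run-length features averaged the same way; 10 GLSZM features
  over 26-connected constant-level zones. Averaging features (not
  matrices) over directions is the dominant convention and is what is
  implemented.
* **Wavelet (480).** A one-level undecimated (stationary) 3D Coiflet-1
  transform with circular boundary handling yields 8 sub-bands
  (`LLL ... HHH`), each the shape of the input; on each sub-band the 21
  first-order features (prefixed `h-`) and 39 texture features are
  recomputed inside the original mask. The high-pass filter is recentred
  to sum to exactly zero in double precision, so constant volumes give
  exactly-zero high-pass sub-bands.

Gray levels are discretized to 32 equal-width bins over the ROI min–max
(`discretization_spec()`); 32 bins is a common radiomics default that keeps
size-zone statistics tractable. The bank's names and counts
(21/15/39/480 → 555 image features; 464 location; 2 clinical; 1021 total)
are contractual and asserted by the test suite.

## Pipeline

1. **Robustness screen.** Each mask is perturbed by 8 slice-wise scenarios:
   (a) +2 columns; (b) +2 columns and +2 rows; (c) 1° and (d) 5° rotation
   about the slice mask centroid (nearest-neighbour resampling); (e) a∘b∘c
   and (f) a∘b∘d; (g) dilation and (h) erosion by the 3×3 cross. For every
   image feature the n-cases × 9-variant matrix feeds a one-way
   random-effects single-measure ICC(1,1) = (MSB − MSW)/(MSB + (k−1)MSW);
   features with ICC > 0.8 pass. The one-way model is used because mask
   variants are algorithmic modifications, not meaningful "raters", and the
   ICC is computed jointly over all 9 variants. Location and clinical
   features are mask-independent and bypass the screen. A case whose
   perturbed ROI degenerates (e.g. erodes away) is excluded with a warning.
2. **Normalization.** Features map to [−1, 1] by
   `x ↦ 2(x − min)/(max − min) − 1`; the (min, max) pairs are stored and
   reapplied, without clipping, to any new data (extensional mode).
   Constant features are dropped with a warning.
3. **Bootstrap importance ranking.** 100 stratified case resamples (with
   replacement), each split into 10 stratified folds; per fold a
   500-tree random forest (impurity importance, √p candidate features per
   split) is fitted on the training part, and the top 25% of that fold's
   importance ranking contribute their importance to a running sum —
   eliminated features contribute 0. With defaults this produces
   100 × 10 = 1000 ranking lists; features are ordered by the accumulated
   contribution.
4. **Sequential forward selection.** Walking the ranking from the top, the
   10-fold CV accuracy of the top-k subset is recorded for every k (folds
   held fixed across k so subsets are compared on identical partitions);
   the smallest k attaining the maximum accuracy is selected (parsimony
   tie-break, matching the very small subsets such models end with). An
   optional `sfs_max_k` caps the walk for exploratory runs; the default
   walks the full ranking.
5. **Evaluation.** The selected subset feeds an outer forest under
   stratified seeded 10-fold CV; each validation case is scored by the
   fraction of trees voting for the positive class (ACP, BRAF-mutant or
   CTNNB1-mutant). Scores are pooled over folds; the ROC/AUC uses the
   pooled scores; threshold metrics (ACC, SENS, SPEC, PPV, NPV, MCC) use
   the strict `score > 0.5` rule (a score of exactly 0.5 is negative). The
   OOB generalization score comes from a single all-cases forest. Folds
   are stratified because with ~12 positives among 44 cases an
   unstratified partition can lose a class. Every score provably
   originates from a fold that excluded its case; the fold bookkeeping is
   returned with the scores and asserted in the tests.
6. **Extensional mode.** New cases are appended and the frozen subsets are
   re-evaluated without re-screening or re-selection.
7. **Nomograms.** A maximum-likelihood logistic model on the selected
   (normalized) features is translated into a point system: feature j maps
   x to `100·|b_j|·(x − ref_j)·sign(b_j)/max_k(|b_k|·range_k)` points with
   `ref_j` the range endpoint giving 0 points, so the most influential
   feature spans exactly 0–100 points and the probability read off the
   total-points axis equals the direct logistic prediction to numerical
   precision. Under complete separation the fit falls back to a lightly
   ridge-penalized likelihood (λ = 10⁻³ on slopes) and is flagged.
   Discrimination is summarized by Harrell's C-index, which for binary
   outcomes equals the ROC AUC. Cohort tables are compared with the
   Mann-Whitney U test (exact when both samples total ≤ 20 without ties,
   tie-corrected normal approximation otherwise) and the Freeman-Halton
   r×c Fisher exact test (probability-mass two-sided criterion by full
   enumeration, Monte-Carlo above 10⁴ total counts).

## The synthetic cohort

The generator (`cohort_config()` / `generate_cohort()`) emulates the
statistical structure of the 44-patient study cohort rather than sellar
anatomy:

* 44 cases, 26 ACP / 18 PCP; in-plane spacing 0.488 mm, 1 mm slices.
* Tumors are blobby ellipsoids (semi-axes 6–11 voxels, boundary modulated
  by a smooth random field, reduced to the 6-connected component
  containing the center), a few thousand voxels each, on a 48×48×36 grid.
  The grid is a desk-scale stand-in for the 512×448 acquisitions; it keeps
  per-case extraction in the sub-second range without changing any
  contract being tested.
* Tumor interiors are Gaussian random fields (white noise convolved with
  an isotropic Gaussian): correlation length 1.0 voxel for ACP and
  1.0 + `texture_contrast` (default 1.5) for PCP — an analytically
  controllable texture difference; PCP adds an `intensity_shift` (default
  60 units on a mean of 600) to the tumor mean. Background is weak noise;
  intensities are clipped to the 16-bit range [0, 65535] but stored as
  reals to avoid quantization artifacts in tolerance tests.
* Ages: PCP ~ N(45, 12), ACP ~ N(45 − `age_effect`, 15), clipped to
  [5, 80] — ACP skews younger, as in the study's pediatric fraction.
  Gender is drawn at the cohort's 29/44 male rate, independent of class
  (the study's gender difference was not significant).
* Labels: PCP ⇔ BRAF-mutant; ACP cases are CTNNB1-mutant except a
  configurable wild/wild leak (default 10/44) standing in for the
  "not detected" group. BRAF and CTNNB1 mutations are therefore mutually
  exclusive by construction. This is a deliberate simplification of the
  real cross-tabulation, in which a few PCPs were CTNNB1-mutant or
  undetected.
* The intensity statistics of real tumors are not published; the defaults
  above are conventions chosen once to give realistic overlap (not
  trivially separable classes), not estimates of any dataset.

What passing tests on this cohort do **not** show: robustness to scanner
effects, bias fields, Rician noise, registration error, or anatomy-driven
confounds — none of which the generator models. They do show that the
pipeline's statistical machinery (screening, ranking, selection,
evaluation, reporting) behaves correctly on data with known structure.

`generate_feature_table()` is the selection test harness: standard-normal
noise columns with a planted informative subset shifted by a configurable
standardized mean difference between balanced classes.

## Numerical choices

* **Surface area.** Meshing a raw binary mask overestimates the area of
  curved surfaces by a direction-dependent constant (≈ +27% for marching
  tetrahedra, ≈ +8.5% for classic marching cubes on spheres), which
  distorts every area-derived shape feature. The package therefore
  triangulates the 0.5 level set of the Gaussian-smoothed indicator
  (σ = 0.9 voxel) with marching tetrahedra; the smoothing places the
  interpolated vertices at sub-voxel positions. Calibrated against the
  analytic sphere, the error falls from +7.7% (r = 5) through +1.2%
  (r = 10) to +0.3% (r = 20), so sphericity approaches 1 with
  monotonically improving error — from slightly above 1 for very small
  ROIs, an acknowledged artifact of smoothing at high curvature. ROIs too
  thin for the smoothed level set (single voxels, one-voxel slabs) fall
  back to the exact exposed voxel-face area.
* **Degenerate inputs.** Zero-variance ROIs: skewness/kurtosis/CV guard to
  0. Texture matrices with a single run/zone stay defined; directions
  yielding no pairs are dropped from the direction average; no feature
  ever returns NaN. An all-equal ICC matrix returns 1. MCC returns 0 when
  a marginal factor of its denominator is 0.
* **Ties.** Vote scores exactly at 0.5 are negative (the positive call is
  strictly "above 0.5"); SFS accuracy ties go to the smaller subset; AUC
  and C-index count score ties 1/2 (midranks), and the trapezoidal ROC
  equals the tie-corrected concordance exactly.
* **Seeds.** One master seed fans out to per-stage seeds by stable string
  hashing (`derive_seed()`), keeping every stage reproducible in isolation
  and all seeds below 2³¹. Fold partitions are keyed by case id, so
  permuting case order changes nothing.

## Evaluating selection quality without optimism

Selecting features on all cases and then cross-validating the selected
subset on the same cases — the protocol radiomics studies commonly report —
is optimistically biased: on pure-noise tables (n = 60, p = 200) it yields
apparent AUCs near 0.87. The package's own quality checks therefore judge a
selected subset on an independent validation table drawn from the same
generator (the extensional-dataset protocol): with 5 informative features
planted at d = 1.5 the recovered subsets still reach validation AUC well
above 0.85, while with no planted signal the validation AUC centers on 0.5.
The in-sample select-then-CV metrics remain available from `run_pipeline()`
for comparability with published tables, but they should be read with that
bias in mind.

## Problem sizes used by the checks

The test suite and `scripts/acceptance.R` run on synthetic cohorts of
10–20 cases with 24³–28³-scale grids (per-case extraction well under a
second), selection studies at n = 60 cases × 200 features with 25
bootstrap resamples and the forward selection capped at the top 60 ranks
(= n cases; CV accuracy cannot resolve subsets larger than the training
set), and validation tables of 200 cases; these sizes were chosen so a
full run stays in the minutes range on a single CPU while leaving every
statistical contrast far from its decision boundary. The
`analysis/` scripts run the full 44-case cohort at the default grid with
the full 100-resample selection.

## Known limitations

* No MR physics: no bias field, no Rician noise, no intensity
  standardization across scanners (a stated future direction for the
  approach this package implements).
* No resampling to isotropic voxels; texture offsets are defined on the
  voxel lattice.
* Registration/atlas construction is out of scope; location features are
  only as good as the supplied region centers.
* The exact published 555-feature definitions are not public; the bank
  here fixes defensible standard definitions containing every feature
  named in the source figures, and the counts are contractual.
* r×c Fisher enumeration is exponential in table size; tables beyond 10⁴
  total counts use the seeded Monte-Carlo fallback with a reported
  standard error.
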