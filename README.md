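# cpradiomics

MRI radiomics for noninvasive diagnosis of craniopharyngioma: classifying
histological subtype (adamantinomatous, **ACP**, vs papillary, **PCP**) and
somatic mutation status (**BRAF V600E**, **CTNNB1**) from a segmented tumor
volume. The two mutations are largely subtype-specific and mutually
exclusive, and BRAF-mutant tumors are candidates for targeted therapy — so
an image-based prediction made before surgery has direct clinical value.

The package implements the full analysis as tested, reusable R functions:

1. **Feature extraction** — 1021 features per case:
   464 location features (for each of 116 atlas region centers, the
   displacement Δ = tumor centroid − center and ‖Δ‖₂), 2 clinical
   covariates, and 555 image features (21 first-order intensity, 15 shape,
   39 texture from GLCM/GLRLM/GLSZM matrices, and 8 × 60 = 480 features on
   the sub-bands of a one-level stationary 3D Coiflet-1 wavelet transform).
2. **Segmentation-robustness screen** — each mask is perturbed by 8
   slice-wise scenarios (±2-pixel translations, 1°/5° rotations, their
   compositions, 1-pixel dilation/erosion); features with one-way
   random-effects ICC(1,1) > 0.8 across the 9 variants are kept:
   ICC = (MSB − MSW) / (MSB + (k − 1) MSW).
3. **Random-forest feature selection** — 100 stratified bootstrap
   resamples × 10-fold CV produce 1000 impurity-importance ranking lists
   (top 25% retained per list); sequential forward selection over the
   summed-contribution ranking picks the smallest subset with maximal
   10-fold CV accuracy.
4. **Evaluation** — stratified 10-fold CV vote-fraction scores
   (fraction of trees voting positive for each held-out case), pooled ROC
   AUC, threshold metrics at the strict score > 0.5 rule
   (ACC/SENS/SPEC/PPV/NPV/MCC), and the out-of-bag generalization score;
   plus an extensional mode that re-evaluates frozen feature subsets on an
   enlarged cohort without re-selection.
5. **Reporting** — logistic nomograms with 0–100 point scales and
   Harrell's C-index, Mann–Whitney U and Freeman–Halton r×c Fisher exact
   tests for cohort tables, and violin/ROC source data.

Because the underlying patient MRI data are not public, the package ships
a seeded synthetic-cohort generator (`generate_cohort()`,
`generate_feature_table()`) that emulates the study's statistical
structure — class-linked texture and intensity contrasts, class-correlated
age, mutually exclusive mutation labels — so every stage is exercised
end-to-end by the tests.

## Worked example

```r
library(cpradiomics)

cohort <- generate_cohort(cohort_config(
  n_cases = 10, image_shape = c(28, 28, 20),
  tumor_radius_range_vox = c(4, 5), seed = 7))
atlas <- generate_atlas_centers(seed = 5)

res <- run_pipeline(cohort, atlas, out_dir = tempfile(),
                    tasks = "pathology",
                    sel_cfg = selection_config(n_bootstrap = 5,
                                               n_trees = 200, seed = 3),
                    eval_seed = 11, n_folds = 5, n_trees = 200)

length(res$pathology$selected)   # size of the selected feature subset
unlist(res$pathology$metrics)
```

prints (the values depend only on the seeds):

```
[1] 2
      auc       acc      sens      spec       ppv       npv       mcc       oob
0.8333333 0.8000000 0.8333333 0.7500000 0.8333333 0.7500000 0.5833333 0.9000000
```

i.e. the screen keeps the mask-robust image features, selection settles on
a 2-feature subset, and the pooled held-out vote scores give AUC 0.83 at
an out-of-bag accuracy of 0.90 on this 10-case cohort. (These are the
in-sample select-then-cross-validate estimates the published protocol
reports; because the subset was chosen on the same 10 cases they are
optimistic — the methods vignette discusses this and the package's
validation-table alternative.) The per-case vote scores, ICC report,
rankings, metrics and the nomogram point scales are written into the run
directory as CSV/JSON.

The `analysis/` directory holds the same workflow as numbered narrative
scripts over a 44-case simulated cohort (`01_simulate.R` …
`07_extended.R`), writing all tables under `results/`.

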