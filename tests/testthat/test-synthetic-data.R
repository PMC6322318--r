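test_that("cohort generation is deterministic and respects the class balance", {
  cfg <- cohort_config(n_cases = 12, image_shape = c(24, 24, 20),
                       tumor_radius_range_vox = c(3.5, 4.5), seed = 7)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1, c2)

  cfg2 <- cohort_config(n_cases = 20, class_balance = 0.5,
                        image_shape = c(24, 24, 20),
                        tumor_radius_range_vox = c(3.5, 4.5), seed = 3)
  coh <- generate_cohort(cfg2)
  expect_equal(sum(vapply(coh, `[[`, "", "label_pathology") == "ACP"), 10)
})

test_that("cohort cases satisfy the label and mask invariants", {
  coh <- tiny_cohort()
  for (case in coh) {
    expect_true(sum(case$mask) > 0)
    expect_equal(count_components6(case$mask), 1)
    expect_false(case$label_braf == "mutant" && case$label_ctnnb1 == "mutant")
    if (case$label_pathology == "PCP") {
      expect_equal(case$label_braf, "mutant")
      expect_equal(case$label_ctnnb1, "wild")
    } else {
      expect_equal(case$label_braf, "wild")
    }
    expect_true(all(case$volume >= 0 & case$volume <= 65535))
    expect_true(case$age_years > 0)
  }
})

test_that("oversized tumors are rejected with a sizing error", {
  expect_error(
    generate_cohort(cohort_config(n_cases = 10, image_shape = c(16, 16, 16),
                                  tumor_radius_range_vox = c(6, 11))),
    "does not fit")
})

test_that("atlas center generation is deterministic and box-bounded", {
  a <- generate_atlas_centers(seed = 5)
  expect_equal(nrow(a), 116)
  expect_false(anyDuplicated(a$label) > 0)
  expect_identical(a, generate_atlas_centers(seed = 5))

  one <- generate_atlas_centers(1, rbind(c(0, 0, 0), c(1, 1, 1)), seed = 2)
  expect_equal(nrow(one), 1)
  expect_true(all(unlist(one[, -1]) >= 0 & unlist(one[, -1]) <= 1))
})

test_that("planted effect sizes are recovered empirically at large n", {
  ft0 <- generate_feature_table(2000, 3, informative = integer(),
                                effect_size = 0, seed = 11)
  d_of <- function(col, labels) {
    a <- col[labels == "pos"]; b <- col[labels == "neg"]
    (mean(a) - mean(b)) / sqrt((var(a) + var(b)) / 2)
  }
  d0 <- vapply(ft0$features, d_of, 0, labels = ft0$labels)
  expect_true(all(abs(d0) < 0.2))

  ft2 <- generate_feature_table(2000, 1, informative = 1, effect_size = 2,
                                seed = 12)
  expect_true(abs(d_of(ft2$features[[1]], ft2$labels) - 2) < 0.1)

  expect_identical(generate_feature_table(50, 4, 1:2, 1, seed = 9),
                   generate_feature_table(50, 4, 1:2, 1, seed = 9))
  expect_error(generate_feature_table(50, 4, informative = 9), "1..n_features")
  expect_error(generate_feature_table(50, 4, 1, effect_size = -1),
               "nonnegative")
})

test_that("cohorts survive a NIfTI round trip", {
  coh <- tiny_cohort()[1:2]
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  back <- read_cohort(dir)
  expect_equal(length(back), 2)
  expect_equal(back[[1]]$case_id, coh[[1]]$case_id)
  expect_equal(back[[1]]$mask, coh[[1]]$mask)
  expect_equal(back[[1]]$volume, coh[[1]]$volume, tolerance = 1e-6)
  expect_equal(back[[1]]$spacing_mm, coh[[1]]$spacing_mm, tolerance = 1e-6)
  expect_equal(back[[2]]$label_pathology, coh[[2]]$label_pathology)
})

test_that("a signal-free cohort yields chance-level downstream discrimination", {
  # null-signal oracle: no texture/intensity/age contrast between classes;
  # first-order features + CV vote scores should sit at AUC ~ 0.5
  aucs <- vapply(1:20, function(s) {
    cfg <- cohort_config(n_cases = 12, class_balance = 0.5,
                         image_shape = c(20, 20, 16),
                         tumor_radius_range_vox = c(3, 3.5),
                         texture_contrast = 0, intensity_shift = 0,
                         age_effect = 0, seed = 100 + s)
    coh <- generate_cohort(cfg)
    x <- as.data.frame(t(vapply(coh, function(k) {
      v <- volume_with_mask(k$volume, k$mask, k$spacing_mm)
      suppressWarnings(intensity_features(v))
    }, numeric(21))))
    labels <- vapply(coh, `[[`, "", "label_pathology")
    sc <- cv_scores(x, labels, positive = "ACP", n_folds = 4, n_trees = 100,
                    seed = s)
    auc_trapezoid(sc$score, sc$label == "ACP")
  }, 0)
  mc_se <- sd(aucs) / sqrt(length(aucs))
  expect_lt(abs(mean(aucs) - 0.5), 3 * mc_se + 1e-12)
})
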