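test_that("normalization maps to [-1, 1] and reapplies to new data", {
  nf <- normalize_features(data.frame(a = c(0, 5, 10), b = c(-1, 0, 1)))
  expect_equal(nf$features$a, c(-1, 0, 1))
  expect_equal(nf$features$b, c(-1, 0, 1))  # extremes already normalized
  out <- apply_normalization(data.frame(a = 12, b = 0), nf$ranges)
  expect_equal(out$a, 1.4)  # no clipping
  expect_warning(nf2 <- normalize_features(data.frame(a = 1:3, k = rep(2, 3))),
                 "constant")
  expect_named(nf2$features, "a")
  expect_error(apply_normalization(data.frame(b = 1), nf$ranges), "missing")
})

test_that("stage 2 ranks a separating feature first and counts its lists", {
  ft <- generate_feature_table(80, 15, informative = integer(),
                               effect_size = 0, seed = 21)
  x <- ft$features
  x$f0001 <- ifelse(ft$labels == "pos", 2, -2) + rnorm(80, 0, 0.1)
  cfg <- selection_config(n_bootstrap = 4, n_folds = 5, n_trees = 100,
                          seed = 31)
  rk <- stage2_rank(x, ft$labels, cfg, positive = "pos")
  expect_equal(rk$feature[1], "f0001")
  expect_equal(attr(rk, "n_lists"), 20)
  expect_setequal(rk$feature, names(x))
  expect_true(all(rk$contribution >= 0))
  expect_true(all(diff(rk$contribution) <= 0))

  single <- stage2_rank(x["f0001"], ft$labels, cfg, positive = "pos")
  expect_equal(single$feature, "f0001")
})

test_that("keep_fraction = 1 reduces stage 2 to plain importance-sum ranking", {
  ft <- generate_feature_table(60, 6, informative = 1, effect_size = 2,
                               seed = 22)
  cfg1 <- selection_config(n_bootstrap = 3, n_folds = 4, n_trees = 100,
                           keep_fraction = 1, seed = 5)
  rk <- stage2_rank(ft$features, ft$labels, cfg1, positive = "pos")
  # nothing is zeroed out: every feature accumulates its raw importance
  expect_true(all(rk$contribution > 0))
  expect_equal(rk$feature[1], "f0001")
})

test_that("stage 3 walks the ranking and prefers the smallest best subset", {
  ft <- generate_feature_table(40, 4, informative = integer(),
                               effect_size = 0, seed = 23)
  x <- ft$features
  x$f0001 <- ifelse(ft$labels == "pos", 5, -5) # wide margin
  cfg <- selection_config(n_bootstrap = 2, n_folds = 5, n_trees = 100,
                          seed = 41)
  ranked <- data.frame(feature = c("f0001", "f0002", "f0003"))
  sfs <- stage3_sfs(x, ft$labels, ranked, cfg, positive = "pos")
  expect_length(sfs$trace, 3)
  expect_equal(sfs$trace[1], 1)
  expect_equal(sfs$features, "f0001")      # ties broken toward parsimony
  expect_equal(sfs$accuracy, max(sfs$trace))
  expect_equal(sfs$k, 1)
})

test_that("selection is deterministic and invariant to case order", {
  ft <- generate_feature_table(40, 10, informative = 1:2, effect_size = 1.5,
                               seed = 24)
  cfg <- selection_config(n_bootstrap = 3, n_folds = 4, n_trees = 100,
                          seed = 51)
  ids <- sprintf("case%03d", seq_len(40))
  run <- function(perm) {
    xp <- ft$features[perm, ]
    lp <- ft$labels[perm]
    rk <- stage2_rank(xp, lp, cfg, positive = "pos", case_ids = ids[perm])
    stage3_sfs(xp, lp, rk, cfg, positive = "pos",
               case_ids = ids[perm])$features
  }
  sel1 <- run(seq_len(40))
  sel2 <- run(seq_len(40))
  expect_identical(sel1, sel2)
  perm <- withr::with_seed(9, sample(40))
  expect_identical(run(perm), sel1)
})

test_that("stage 3 caps at sfs_max_k when configured", {
  ft <- generate_feature_table(30, 8, informative = integer(),
                               effect_size = 0, seed = 25)
  cfg <- selection_config(n_bootstrap = 2, n_folds = 3, n_trees = 50,
                          sfs_max_k = 4, seed = 6)
  rk <- stage2_rank(ft$features, ft$labels, cfg, positive = "pos")
  sfs <- stage3_sfs(ft$features, ft$labels, rk, cfg, positive = "pos")
  expect_length(sfs$trace, 4)
})
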