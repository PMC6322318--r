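sep_toy <- function(n = 40, gap = 5, seed = 17) {
  withr::with_seed(seed, {
    x <- data.frame(f1 = c(rnorm(n / 2, -gap), rnorm(n / 2, gap)),
                    f2 = rnorm(n))
    list(x = x, labels = rep(c("wild", "mutant"), each = n / 2))
  })
}

test_that("separable classes get separated vote scores", {
  toy <- sep_toy()
  sc <- cv_scores(toy$x, toy$labels, positive = "mutant", n_folds = 5,
                  n_trees = 101, seed = 3)
  expect_true(all(sc$score[sc$label == "mutant"] > 0.5))
  expect_true(all(sc$score[sc$label == "wild"] < 0.5))
  expect_true(all(sc$score >= 0 & sc$score <= 1))
  expect_equal(nrow(sc), 40)
})

test_that("a one-tree forest yields {0,1} scores and folds are near-equal", {
  toy <- sep_toy(44)
  sc <- cv_scores(toy$x, toy$labels, positive = "mutant", n_folds = 10,
                  n_trees = 1, seed = 5)
  expect_true(all(sc$score %in% c(0, 1)))
  sizes <- table(sc$fold)
  expect_lte(max(sizes) - min(sizes), 1)
  expect_equal(length(sizes), 10)
})

test_that("classification is strictly above the 0.5 threshold", {
  expect_true(classify(0.51))
  expect_false(classify(0.5))
  expect_equal(classify(c(1, 1, 1)), rep(TRUE, 3))
  expect_equal(classify(c(0.2, 0, 0.6), threshold = 0), c(TRUE, FALSE, TRUE))
})

test_that("AUC matches pair counting and metrics match closed forms", {
  mk_scores <- function(score, label) {
    structure(data.frame(case_id = seq_along(score), score = score,
                         fold = 1, label = label),
              positive = "pos")
  }
  s1 <- mk_scores(c(0.9, 0.8, 0.4, 0.7), c("pos", "pos", "neg", "neg"))
  expect_equal(auc_trapezoid(s1$score, s1$label == "pos"), 1)
  s2 <- mk_scores(c(0.8, 0.3, 0.5, 0.2), c("pos", "pos", "neg", "neg"))
  expect_equal(auc_trapezoid(s2$score, s2$label == "pos"), 0.75)

  s3 <- mk_scores(c(0.9, 0.8, 0.3, 0.6, 0.7, 0.2),
                  c("pos", "pos", "pos", "neg", "neg", "neg"))
  m <- compute_metrics(s3, predictions = c(TRUE, TRUE, FALSE, TRUE, FALSE,
                                           FALSE))
  expect_equal(m$acc, 4 / 6)
  expect_equal(m$mcc, 3 / 9)
  expect_equal(m$sens, 2 / 3)
  expect_equal(m$spec, 2 / 3)
})

test_that("the trapezoidal AUC agrees with pROC on random score sets", {
  withr::with_seed(21, {
    for (i in 1:10) {
      n <- sample(10:50, 1)
      score <- round(runif(n), 2)
      pos <- runif(n) > 0.4
      if (!any(pos) || all(pos)) next
      ref <- as.numeric(pROC::auc(pROC::roc(response = pos,
                                            predictor = score,
                                            quiet = TRUE,
                                            direction = "<")))
      expect_equal(auc_trapezoid(score, pos), ref, tolerance = 1e-12)
    }
  })
})

test_that("swapping the positive class swaps SENS/SPEC and PPV/NPV", {
  sc <- withr::with_seed(8, {
    structure(data.frame(case_id = 1:20, score = runif(20), fold = 1,
                         label = rep(c("mutant", "wild"), 10)),
              positive = "mutant")
  })
  pred <- classify(sc)
  swapped <- structure(transform(sc, score = 1 - score), positive = "wild")
  m1 <- compute_metrics(sc, pred)
  m2 <- compute_metrics(swapped, !pred)
  expect_equal(m1$sens, m2$spec)
  expect_equal(m1$spec, m2$sens)
  expect_equal(m1$ppv, m2$npv)
  expect_equal(m1$npv, m2$ppv)
  expect_equal(m1$acc, m2$acc)
  expect_true(all(unlist(m1[c("sens", "spec", "ppv", "npv", "acc")]) >= 0 &
                    unlist(m1[c("sens", "spec", "ppv", "npv", "acc")]) <= 1))
})

test_that("OOB score separates signal from chance", {
  toy <- sep_toy()
  expect_gte(oob_score(toy$x, toy$labels, "mutant", n_trees = 201, seed = 4),
             0.9)
  expect_equal(oob_score(toy$x, toy$labels, "mutant", n_trees = 201, seed = 4),
               oob_score(toy$x, toy$labels, "mutant", n_trees = 201, seed = 4))
  oobs <- vapply(1:10, function(s) {
    labs <- withr::with_seed(1000 + s, sample(toy$labels))
    oob_score(toy$x, labs, "mutant", n_trees = 101, seed = s)
  }, 0)
  expect_lt(abs(mean(oobs) - 0.5), 3 * sd(oobs) / sqrt(10) + 0.05)
})

test_that("every score comes from a fold that excluded its case", {
  toy <- sep_toy(30, seed = 12)
  sc <- cv_scores(toy$x, toy$labels, positive = "mutant", n_folds = 6,
                  n_trees = 51, seed = 7)
  ft <- attr(sc, "fold_train")
  expect_length(ft, 6)
  for (i in seq_len(nrow(sc)))
    expect_false(sc$case_id[i] %in% ft[[sc$fold[i]]])
  expect_equal(sort(unique(sc$case_id)), sort(sc$case_id)) # scored once
})

test_that("the extensional protocol freezes features and flags missing ones", {
  toy <- sep_toy()
  main <- evaluate_model(toy$x, toy$labels, "mutant", n_folds = 5,
                         n_trees = 101, seed = 9)
  ext <- evaluate_extended(c("f1", "f2"), toy$x, toy$labels, "mutant",
                           n_folds = 5, n_trees = 101, seed = 9)
  expect_equal(main$metrics, ext$metrics)  # identity extension
  expect_error(evaluate_extended(c("f1", "nope"), toy$x, toy$labels,
                                 "mutant"), "nope")
})

test_that("diluting the cohort with label-shuffled cases does not help", {
  deltas <- vapply(1:8, function(s) {
    toy <- sep_toy(24, gap = 1.2, seed = 300 + s)
    m_main <- evaluate_model(toy$x, toy$labels, "mutant", n_folds = 4,
                             n_trees = 101, seed = s)$metrics$auc
    extra <- withr::with_seed(400 + s, {
      data.frame(f1 = rnorm(16, 0, 2), f2 = rnorm(16))
    })
    x2 <- rbind(toy$x, extra)
    lab2 <- c(toy$labels, rep(c("wild", "mutant"), 8))
    m_ext <- evaluate_extended(c("f1", "f2"), x2, lab2, "mutant",
                               n_folds = 4, n_trees = 101,
                               seed = s)$metrics$auc
    m_ext - m_main
  }, 0)
  expect_lte(mean(deltas), 0.02) # non-increase in expectation
})
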