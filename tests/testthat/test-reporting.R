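logit_toy <- function(n = 60, seed = 4) {
  withr::with_seed(seed, {
    x <- data.frame(a = runif(n, -1, 1), b = runif(n, -1, 1))
    lp <- 0.5 + 2 * x$a - x$b
    labels <- ifelse(runif(n) < plogis(lp), "ACP", "PCP")
    list(x = x, labels = labels)
  })
}

test_that("point scales follow the max-100 normalization", {
  ps <- cpradiomics:::nomogram_point_scale(c(a = 2, b = 1),
                                           lo = c(-1, -1), hi = c(1, 1))
  expect_equal(ps$table$max_points, c(100, 50))
  # doubling every coefficient leaves the point scale unchanged
  ps2 <- cpradiomics:::nomogram_point_scale(c(a = 4, b = 2),
                                            lo = c(-1, -1), hi = c(1, 1))
  expect_equal(ps2$table$max_points, ps$table$max_points)
  # beta = 0 gives a flat zero-point scale
  ps0 <- cpradiomics:::nomogram_point_scale(c(a = 2, b = 0),
                                            lo = c(-1, -1), hi = c(1, 1))
  expect_equal(ps0$table$max_points[2], 0)
})

test_that("total points reproduce the direct logistic prediction", {
  toy <- logit_toy()
  nm <- fit_nomogram(toy$x, toy$labels, positive = "ACP")
  direct <- plogis(as.numeric(cbind(1, as.matrix(toy$x)) %*%
                                nm$coefficients))
  expect_lt(max(abs(nm$prob_of_points(nm$points_of(toy$x)) - direct)), 1e-9)
  expect_equal(max(nm$point_scale$max_points), 100)
  expect_false(nm$separated)
  # the probability curve is monotone in total points
  grid <- seq(min(nm$total_points), max(nm$total_points), length.out = 50)
  expect_true(all(diff(nm$prob_of_points(grid)) >= 0))
})

test_that("complete separation falls back to a flagged ridge fit", {
  x <- data.frame(a = c(rep(-1, 10), rep(1, 10)))
  labels <- rep(c("PCP", "ACP"), each = 10)
  nm <- fit_nomogram(x, labels, positive = "ACP")
  expect_true(nm$separated)
  expect_true(all(is.finite(unlist(nm$coefficients))))
  expect_gte(nm$c_index, 0.99)
})

test_that("the C-index is the tie-aware concordance", {
  expect_equal(c_index(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(c_index(rep(0.3, 6), rep(c(TRUE, FALSE), 3)), 0.5)
  withr::with_seed(11, {
    for (i in 1:20) {
      p <- round(runif(30), 1) # ties on purpose
      y <- runif(30) > 0.5
      if (!any(y) || all(y)) next
      expect_equal(c_index(p, y), auc_trapezoid(p, y), tolerance = 1e-12)
    }
  })
  expect_error(c_index(1:3 / 3, c(TRUE, TRUE, TRUE)), "both")
})

test_that("Mann-Whitney matches enumeration and symmetry", {
  mw <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 1 / 3)
  same <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$U, 4.5)  # n_x n_y / 2 under ties
  expect_equal(same$p, 1)
  a <- c(2, 5, 9); b <- c(1, 4, 6, 7)
  expect_equal(mann_whitney_u(a, b)$U + mann_whitney_u(b, a)$U,
               length(a) * length(b))
  expect_equal(mann_whitney_u(a, b)$p, mann_whitney_u(b, a)$p)
  expect_error(mann_whitney_u(numeric(), 1), "non-empty")
})

test_that("the Freeman-Halton test matches hand enumeration", {
  expect_equal(fisher_exact_rxc(matrix(c(5, 5, 5, 5), 2, 2)), 1)
  expect_equal(fisher_exact_rxc(matrix(c(2, 0, 0, 2), 2, 2)), 1 / 3,
               tolerance = 1e-12)
  p <- fisher_exact_rxc(matrix(c(9, 14, 6, 3, 8, 4), 3, 2))
  expect_true(p >= 0 && p <= 1)
  expect_error(fisher_exact_rxc(matrix(c(1, -1, 2, 2), 2, 2)), "nonnegative")
})

test_that("the Monte-Carlo fallback approximates the exact test", {
  tab <- matrix(c(6000, 5900, 6100, 6050), 2, 2)
  p_mc <- fisher_exact_rxc(tab, max_total = 10000, mc_draws = 20000, seed = 2)
  expect_true(!is.null(attr(p_mc, "mc_se")))
  p_ref <- stats::fisher.test(tab)$p.value
  expect_lt(abs(as.numeric(p_mc) - p_ref), 0.02)
})
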