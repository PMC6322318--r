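px <- function(r, c, dims = c(20, 20, 3), z = 2) {
  m <- array(FALSE, dims); m[r, c, z] <- TRUE; m
}

test_that("perturbation scenarios act as defined on single pixels", {
  m <- px(10, 10)
  expect_equal(which(perturb_mask(m, "a")[, , 2], arr.ind = TRUE)[1, ],
               c(row = 10, col = 12))
  expect_equal(which(perturb_mask(m, "b")[, , 2], arr.ind = TRUE)[1, ],
               c(row = 12, col = 12))
  expect_identical(perturb_mask(m, "c"), m)  # rotation about the centroid
  g <- perturb_mask(m, "g")
  expect_equal(sum(g), 5)                    # city-block cross
  expect_identical(perturb_mask(g, "h"), m)  # erosion undoes the dilation
  expect_error(perturb_mask(m, "h"), "degenerate")
  expect_equal(which(perturb_mask(m, "e")[, , 2], arr.ind = TRUE)[1, ],
               c(row = 12, col = 14))        # a, b then c; rotation fixed point
})

test_that("translations preserve counts away from the boundary; g grows, h shrinks", {
  coh <- tiny_cohort()
  m <- coh[[1]]$mask
  for (s in c("a", "b", "e", "f"))
    expect_equal(sum(perturb_mask(m, s)), sum(m))
  expect_gt(sum(perturb_mask(m, "g")), sum(m))
  expect_lt(sum(perturb_mask(m, "h")), sum(m))
  expect_equal(length(perturbation_scenarios()), 8)
})

test_that("ICC(1,1) matches the one-way ANOVA closed form", {
  expect_equal(icc(matrix(c(1, 3, 5, 2, 4, 6), 3, 2)), 7.5 / 8.5)
  expect_equal(icc(matrix(c(1, 2, 1, 2), 2, 2)), 1)  # identical columns
  expect_equal(icc(matrix(3, 2, 2)), 1)              # all-constant guard
  expect_error(icc(matrix(1, 1, 2)), ">= 2")
})

test_that("ICC is invariant to permutations and affine rescaling", {
  withr::with_seed(4, {
    m <- matrix(rnorm(40), 10, 4) + rnorm(10) # subject effects
    v0 <- icc(m)
    expect_equal(icc(m[sample(10), ]), v0)
    expect_equal(icc(m[, sample(4)]), v0)
    expect_equal(icc(3 * m + 7), v0)
  })
})

test_that("ICC of pure noise concentrates near zero", {
  withr::with_seed(8, {
    vals <- replicate(30, icc(matrix(rnorm(200 * 3), 200, 3)))
  })
  expect_lt(abs(mean(vals)), 3 * sd(vals) / sqrt(30) + 0.02)
})

test_that("the robustness screen separates stable from noisy features", {
  coh <- tiny_cohort()[1:4]
  cases <- lapply(coh, function(k)
    volume_with_mask(k$volume, k$mask, k$spacing_mm))
  # injected extractor: one mask-independent feature, one per-call noise
  counter <- new.env(); counter$i <- 0
  fake <- function(v, d) {
    counter$i <- counter$i + 1
    c(stable = sum(v$intensities),
      noisy = withr::with_seed(counter$i, rnorm(1)))
  }
  rep <- robustness_screen(cases, extractor = fake)
  expect_equal(nrow(rep), 2)
  expect_true(rep$pass[rep$feature == "stable"])
  expect_equal(rep$icc[rep$feature == "stable"], 1)
  expect_false(rep$pass[rep$feature == "noisy"])
  expect_true(all(rep$pass == (rep$icc > 0.8)))
})

test_that("the full screen partitions the 555 image features", {
  coh <- tiny_cohort()[1:3]
  cases <- lapply(coh, function(k)
    volume_with_mask(k$volume, k$mask, k$spacing_mm))
  rep <- memo("icc_report3", robustness_screen(cases))
  expect_equal(nrow(rep), 555)
  expect_true(all(rep$icc <= 1 + 1e-12))
  expect_equal(sum(rep$pass) + sum(!rep$pass), 555)
  expect_true(all(rep$category %in% c("intensity", "shape", "texture",
                                      "wavelet")))
})

test_that("noise features fail the screen at realistic cohort sizes", {
  # n = 50 pseudo-cases: the ICC of fresh per-variant noise is ~ 0, far
  # below the 0.8 robustness threshold
  withr::with_seed(15, {
    iccs <- replicate(20, icc(matrix(rnorm(50 * 9), 50, 9)))
  })
  expect_true(all(iccs < 0.8))
})
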