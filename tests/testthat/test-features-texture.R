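test_that("GLCM dissimilarity matches hand enumeration on a 2x2 slab", {
  # grid rows (1,2) in each column: horizontal pairs equal, vertical differ
  a <- array(c(1, 2, 1, 2), c(2, 2, 1))
  v <- volume_with_mask(a, array(TRUE, c(2, 2, 1)))
  d <- discretization_spec(2)
  dis <- function(p) { i <- matrix(seq_len(nrow(p)), nrow(p), nrow(p))
                       sum(abs(i - t(i)) * p) }
  expect_equal(dis(glcm_matrix(v, d, c(0, 1, 0))), 0)
  expect_equal(dis(glcm_matrix(v, d, c(1, 0, 0))), 1)
  expect_equal(mean(c(0, 1)), 0.5)
})

test_that("GLCM matrices are symmetric and margin-normalized", {
  v <- toy_volume(3)
  d <- discretization_spec(8)
  offs <- cpradiomics:::offsets13()
  for (k in seq_len(nrow(offs))) {
    p <- glcm_matrix(v, d, offs[k, ])
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_equal(p, t(p))
  }
})

test_that("GLRLM runs match hand enumeration", {
  a <- array(c(1, 1, 2), c(1, 3, 1))
  v <- volume_with_mask(a, array(TRUE, c(1, 3, 1)))
  d <- discretization_spec(2)
  r <- glrlm_matrix(v, d, c(0, 1, 0))
  expect_equal(sum(r), 2)                 # two runs: (1,len2), (2,len1)
  expect_equal(r[1, 2], 1)
  expect_equal(r[2, 1], 1)
  p <- r / sum(r)
  gl <- matrix(seq_len(nrow(r)), nrow(r), ncol(r))
  rl <- matrix(seq_len(ncol(r)), nrow(r), ncol(r), byrow = TRUE)
  expect_equal(sum(p / (gl^2 * rl^2)), 0.25)  # SRLGE by hand
})

test_that("GLSZM zones are 26-connected", {
  a <- array(0, c(4, 4, 1))
  a[1, 1, 1] <- 1; a[2, 2, 1] <- 1  # diagonal touch: one zone
  a[4, 4, 1] <- 1                   # far corner: separate zone
  m <- a > 0
  a[m] <- 5
  v <- volume_with_mask(a, m)
  z <- glszm_zones(v, discretization_spec(2))
  expect_equal(nrow(z), 2)
  expect_setequal(z[, 2], c(2, 1))
})

test_that("constant ROI texture is degenerate but defined", {
  v <- volume_with_mask(array(3, c(4, 4, 2)), array(TRUE, c(4, 4, 2)))
  f <- texture_features(v)
  expect_length(f, 39)
  expect_named(f, TEXTURE_FEATURE_NAMES)
  expect_equal(unname(f["contrast"]), 0)
  expect_equal(unname(f["maximum_probability"]), 1)
  expect_true(all(is.finite(f)))
})

test_that("tiny ROIs never produce NaN", {
  m <- array(FALSE, c(5, 5, 3)); m[2, 2, 2] <- TRUE; m[3, 2, 2] <- TRUE
  v <- volume_with_mask(array(rnorm(75), c(5, 5, 3)), m)
  expect_true(all(is.finite(texture_features(v))))
  m1 <- array(FALSE, c(5, 5, 3)); m1[2, 2, 2] <- TRUE
  expect_error(texture_features(volume_with_mask(array(0, c(5, 5, 3)), m1)),
               ">= 2")
})
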