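INTENSITY_FEATURE_NAMES <- c(
  "minimum", "maximum", "range", "mean", "median",
  "percentile10", "percentile90", "interquartile_range",
  "variance", "standard_deviation",
  "mean_absolute_deviation", "robust_mean_absolute_deviation",
  "root_mean_square", "energy", "total_energy",
  "skewness", "kurtosis", "entropy", "uniformity",
  "coefficient_of_variation", "voxel_count")

#' First-order intensity features (21 values)
#'
#' Statistics of the in-mask intensity distribution. Moments use the
#' population (n) denominator; kurtosis is Pearson (non-excess, so a
#' Gaussian scores 3); entropy and uniformity are computed over the
#' discretization histogram; `total_energy` scales the sum of squares by the
#' voxel volume in mm^3. A zero-variance ROI returns skewness and kurtosis 0
#' with a warning, and the coefficient of variation is 0 when the mean is 0.
#'
#' @param v a [volume_with_mask()]
#' @param d a [discretization_spec()] (for the entropy/uniformity histogram)
#' @return named numeric vector of length 21
#' @export
intensity_features <- function(v, d = discretization_spec()) {
  x <- in_mask(v)
  if (length(x) == 0) stopf("mask is empty")
  n <- length(x)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  q <- unname(quantile(x, c(0.1, 0.25, 0.5, 0.75, 0.9), type = 7))
  if (m2 > 0) {
    skew <- mean((x - mu)^3) / m2^1.5
    kurt <- mean((x - mu)^4) / m2^2
  } else {
    warnf("zero-variance ROI: skewness and kurtosis set to 0")
    skew <- 0
    kurt <- 0
  }
  robust <- x[x >= q[1] & x <= q[5]]
  lv <- tabulate(discretize_roi(v$intensities, v$mask, d)[v$mask],
                 nbins = d$n_levels)
  p <- lv[lv > 0] / n
  energy <- sum(x^2)
  out <- c(
    min(x), max(x), max(x) - min(x), mu, q[3],
    q[1], q[5], q[4] - q[2],
    m2, sqrt(m2),
    mean(abs(x - mu)), mean(abs(robust - mean(robust))),
    sqrt(mean(x^2)), energy, energy * voxel_volume_mm3(v),
    skew, kurt, -sum(p * log2(p)), sum(p^2),
    if (mu != 0) sqrt(m2) / mu else 0, n)
  names(out) <- INTENSITY_FEATURE_NAMES
  out
}
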