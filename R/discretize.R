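#' Gray-level discretization settings for texture features
#'
#' Intensities inside the ROI are binned into `n_levels` equal-width levels
#' over the ROI min-max range before any co-occurrence, run-length or
#' size-zone matrix is built, and for the first-order entropy/uniformity
#' histogram.
#'
#' @param n_levels number of gray levels (>= 2); default 32, a common
#'   radiomics choice that keeps size-zone statistics tractable
#' @param range_policy how the binning range is chosen; only `"roi-min-max"`
#'   is defined
#' @return an object of class `discretization_spec`
#' @export
discretization_spec <- function(n_levels = 32, range_policy = "roi-min-max") {
  n_levels <- check_count(n_levels, "n_levels", min = 2)
  range_policy <- match.arg(range_policy, "roi-min-max")
  structure(list(n_levels = n_levels, range_policy = range_policy),
            class = "discretization_spec")
}

# Integer level array: 0 outside the mask, 1..n_levels inside. A constant ROI
# maps entirely to level 1.
discretize_roi <- function(intensities, mask, spec) {
  vals <- intensities[mask]
  lv <- array(0L, dim(mask))
  if (length(vals) == 0) return(lv)
  lo <- min(vals); hi <- max(vals)
  if (hi - lo <= 0) {
    lv[mask] <- 1L
  } else {
    b <- floor((intensities[mask] - lo) / (hi - lo) * spec$n_levels) + 1L
    lv[mask] <- pmin(as.integer(b), spec$n_levels)
  }
  lv
}
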