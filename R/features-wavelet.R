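WAVELET_BANDS <- c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH")

# Coiflet-1 analysis filter bank. The high-pass filter sums to zero
# analytically; to make that exact in floating point it is applied as its
# cumulative kernel on the first-differenced signal (see hp_filter_axis),
# so `hi` is stored as the 5-tap cumulative form.
coif1_filters <- function() {
  lo <- c(-0.015655728135465, -0.072732619512854, 0.384864846864203,
          0.852572020212255, 0.337897662457809, -0.072732619512854)
  hi <- c(0.072732619512854, 0.337897662457809, -0.852572020212255,
          0.384864846864203, 0.072732619512854, -0.015655728135465)
  # h_t = G_t - G_{t-1} with G_0 = G_6 = 0, so
  # (h * x)[i] = sum_t -G_t (x[i+t-2] - x[i+t-3]): a 5-tap filter on the
  # circular first difference. A constant input differences to exact zero.
  list(lo = lo, hi_cum = -cumsum(hi)[1:5])
}

# high-pass filtering along one axis via the difference form (circular)
hp_filter_axis <- function(a, hi_cum, ax) {
  d <- dim(a)
  idx <- lapply(d, seq_len)
  idx[[ax]] <- c(seq_len(d[ax])[-1], 1L)
  dx <- do.call(`[`, c(list(a), idx)) - a
  filter_axis(dx, hi_cum, ax, circular = TRUE)
}

#' One-level undecimated 3D wavelet transform (Coiflet-1)
#'
#' Stationary (no decimation) separable transform with circular boundary
#' handling: each axis is filtered with the low- or high-pass Coiflet-1
#' analysis filter, producing 8 sub-bands `LLL ... HHH`, each the same shape
#' as the input. The band letter order follows the axis order of the array.
#'
#' @param a numeric 3D array (at least 8 voxels per axis)
#' @return named list of 8 arrays
#' @export
swt3 <- function(a) {
  if (any(dim(a) < 8)) stopf("wavelet transform needs >= 8 voxels per axis")
  fl <- coif1_filters()
  bands <- list(a)
  tags <- ""
  for (ax in 1:3) {
    nxt <- vector("list", 2 * length(bands))
    ntags <- character(2 * length(bands))
    for (i in seq_along(bands)) {
      nxt[[2 * i - 1]] <- filter_axis(bands[[i]], fl$lo, ax, circular = TRUE)
      nxt[[2 * i]] <- hp_filter_axis(bands[[i]], fl$hi_cum, ax)
      ntags[2 * i - 1] <- paste0(tags[i], "L")
      ntags[2 * i] <- paste0(tags[i], "H")
    }
    bands <- nxt
    tags <- ntags
  }
  names(bands) <- tags
  bands[WAVELET_BANDS]
}

wavelet_feature_names <- function() {
  unlist(lapply(WAVELET_BANDS, function(b) {
    c(paste0(b, "_h-", INTENSITY_FEATURE_NAMES),
      paste0(b, "_", TEXTURE_FEATURE_NAMES))
  }), use.names = FALSE)
}

#' Wavelet features (480 values)
#'
#' On each of the 8 stationary-wavelet sub-bands, the 21 first-order
#' features (prefixed `h-`, e.g. `HHH_h-mean`) and the 39 texture features
#' are recomputed within the original tumor mask, with the discretization
#' range taken from the sub-band's own ROI min-max.
#'
#' @param v a [volume_with_mask()]
#' @param d a [discretization_spec()]
#' @param subbands optional precomputed [swt3()] output for `v$intensities`
#'   (the transform does not depend on the mask, so callers evaluating many
#'   mask variants can reuse it)
#' @return named numeric vector of length 480
#' @export
wavelet_features <- function(v, d = discretization_spec(), subbands = NULL) {
  subbands <- subbands %||% swt3(v$intensities)
  out <- unlist(lapply(WAVELET_BANDS, function(b) {
    vb <- volume_with_mask(subbands[[b]], v$mask, v$spacing_mm)
    c(suppressWarnings(intensity_features(vb, d)), texture_features(vb, d))
  }), use.names = FALSE)
  names(out) <- wavelet_feature_names()
  out
}
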