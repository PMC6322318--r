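#' The eight segmentation-perturbation scenarios
#'
#' Slice-wise (axial-plane) modifications of the tumor mask used for the
#' robustness screen: (a) horizontal translation by 2 pixels; (b) horizontal
#' and vertical translation by 2 pixels; (c) 1 degree rotation; (d) 5 degree
#' rotation; (e) a, b then c; (f) a, b then d; (g) dilation by 1 pixel;
#' (h) erosion by 1 pixel.
#'
#' @return named list of scenario descriptors
#' @export
perturbation_scenarios <- function() {
  list(
    a = list(id = "a", translate = c(0, 2), rotate = 0, morph = 0),
    b = list(id = "b", translate = c(2, 2), rotate = 0, morph = 0),
    c = list(id = "c", translate = c(0, 0), rotate = 1, morph = 0),
    d = list(id = "d", translate = c(0, 0), rotate = 5, morph = 0),
    e = list(id = "e", translate = c(2, 4), rotate = 1, morph = 0),
    f = list(id = "f", translate = c(2, 4), rotate = 5, morph = 0),
    g = list(id = "g", translate = c(0, 0), rotate = 0, morph = +1),
    h = list(id = "h", translate = c(0, 0), rotate = 0, morph = -1))
}

translate_slice <- function(s, dr, dc) {
  out <- array(FALSE, dim(s))
  nr <- nrow(s); nc <- ncol(s)
  rs <- seq_len(nr) - dr
  cs <- seq_len(nc) - dc
  rok <- rs >= 1 & rs <= nr
  cok <- cs >= 1 & cs <= nc
  out[which(rok), which(cok)] <- s[rs[rok], cs[cok]]
  out
}

rotate_slice <- function(s, degrees) {
  if (!any(s)) return(s)
  idx <- which(s, arr.ind = TRUE)
  ctr <- colMeans(idx)
  th <- degrees * pi / 180
  co <- cos(-th); si <- sin(-th) # inverse map for target sampling
  nr <- nrow(s); nc <- ncol(s)
  g <- expand.grid(r = seq_len(nr), c = seq_len(nc))
  rr <- ctr[1] + co * (g$r - ctr[1]) - si * (g$c - ctr[2])
  cc <- ctr[2] + si * (g$r - ctr[1]) + co * (g$c - ctr[2])
  ri <- round(rr); ci <- round(cc)
  ok <- ri >= 1 & ri <= nr & ci >= 1 & ci <= nc
  out <- array(FALSE, dim(s))
  out[cbind(g$r[ok], g$c[ok])] <- s[cbind(ri[ok], ci[ok])]
  out
}

morph_slice <- function(s, grow) {
  nbr <- function(m) {
    up <- rbind(m[-1, , drop = FALSE], FALSE)
    dn <- rbind(FALSE, m[-nrow(m), , drop = FALSE])
    lf <- cbind(m[, -1, drop = FALSE], FALSE)
    rt <- cbind(FALSE, m[, -ncol(m), drop = FALSE])
    list(up, dn, lf, rt)
  }
  n <- nbr(s)
  if (grow > 0) s | n[[1]] | n[[2]] | n[[3]] | n[[4]]
  else s & n[[1]] & n[[2]] & n[[3]] & n[[4]]
}

#' Apply one perturbation scenario to a 3D mask
#'
#' Perturbations act slice-wise in the axial plane (third array dimension
#' indexes slices): translations shift rows ("vertical") and columns
#' ("horizontal"); rotations are about the slice's own mask centroid with
#' nearest-neighbour resampling; dilation/erosion use the 3x3 cross
#' (city-block radius 1). Voxels pushed outside the grid are dropped.
#'
#' @param mask logical 3D array
#' @param scenario a single letter `"a"`..`"h"` or an element of
#'   [perturbation_scenarios()]
#' @return perturbed logical array of the same shape
#' @export
perturb_mask <- function(mask, scenario) {
  if (is.character(scenario)) {
    sc <- perturbation_scenarios()[[scenario]]
    if (is.null(sc)) stopf("unknown scenario '%s'", scenario)
  } else sc <- scenario
  out <- mask
  for (z in seq_len(dim(mask)[3])) {
    s <- mask[, , z]
    if (any(sc$translate != 0)) s <- translate_slice(s, sc$translate[1],
                                                     sc$translate[2])
    if (sc$rotate != 0) s <- rotate_slice(s, sc$rotate)
    if (sc$morph != 0) s <- morph_slice(s, sc$morph)
    out[, , z] <- s
  }
  if (!any(out)) stopf("perturbation '%s' produced a degenerate (empty) ROI",
                       sc$id)
  out
}

#' One-way random-effects single-measure intraclass correlation ICC(1,1)
#'
#' `(MSB - MSW) / (MSB + (k - 1) MSW)` from the one-way ANOVA decomposition
#' of an n-subjects x k-variants matrix. An all-constant matrix returns 1.
#'
#' @param m numeric matrix, n >= 2 rows (subjects), k >= 2 columns (mask
#'   variants), no missing values
#' @return a single number <= 1
#' @export
icc <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 2 || ncol(m) < 2) stopf("icc needs >= 2 rows and >= 2 columns")
  if (any(!is.finite(m))) stopf("icc input must be finite")
  n <- nrow(m); k <- ncol(m)
  rm_ <- rowMeans(m)
  msb <- k * sum((rm_ - mean(m))^2) / (n - 1)
  msw <- sum((m - rm_)^2) / (n * (k - 1))
  if (msb == 0 && msw == 0) return(1)
  (msb - msw) / (msb + (k - 1) * msw)
}

#' Stage-1 selection: segmentation-robustness screen
#'
#' For every image feature, builds the n-cases x 9 matrix of feature values
#' on the original mask and the 8 perturbed masks, computes ICC(1,1) jointly
#' over the 9 variants, and flags features with ICC > 0.8 as robust.
#' Location and clinical features are mask-independent and bypass the
#' screen. A case whose perturbed ROI degenerates (e.g. fully eroded) is
#' excluded with a warning.
#'
#' @param cases list of [volume_with_mask()] (>= 2)
#' @param d a [discretization_spec()]
#' @param extractor feature extractor; defaults to
#'   [extract_image_features()]. If it accepts a `subbands` argument the
#'   wavelet transform is computed once per case and shared across the 9
#'   mask variants.
#' @param icc_threshold pass threshold (exclusive); default 0.8
#' @return data.frame (`feature`, `category`, `icc`, `pass`)
#' @export
robustness_screen <- function(cases, d = discretization_spec(),
                              extractor = extract_image_features,
                              icc_threshold = 0.8) {
  if (length(cases) < 2) stopf("robustness screen needs >= 2 cases")
  takes_subbands <- "subbands" %in% names(formals(extractor))
  scen <- perturbation_scenarios()
  per_case <- lapply(seq_along(cases), function(i) {
    v <- cases[[i]]
    sb <- if (takes_subbands) swt3(v$intensities) else NULL
    run <- function(m) {
      vv <- volume_with_mask(v$intensities, m, v$spacing_mm)
      if (takes_subbands) extractor(vv, d, subbands = sb)
      else extractor(vv, d)
    }
    variants <- tryCatch({
      masks <- c(list(v$mask), lapply(scen, function(s) perturb_mask(v$mask, s)))
      lapply(masks, run)
    }, error = function(e) {
      warnf("case %d excluded from robustness screen: %s", i, conditionMessage(e))
      NULL
    })
    variants
  })
  per_case <- per_case[!vapply(per_case, is.null, TRUE)]
  if (length(per_case) < 2) stopf("fewer than 2 usable cases after exclusions")
  feats <- names(per_case[[1]][[1]])
  iccs <- vapply(seq_along(feats), function(j) {
    m <- t(vapply(per_case, function(vr) vapply(vr, `[[`, 0, j),
                  numeric(9)))
    icc(m)
  }, 0)
  data.frame(feature = feats,
             category = feature_category(feats),
             icc = iccs,
             pass = iccs > icc_threshold,
             stringsAsFactors = FALSE)
}
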