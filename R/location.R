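#' Tumor center in physical space
#'
#' Intensity-unweighted centroid of the mask voxel centers, mapped through a
#' voxel-to-mm affine. The default affine scales 0-based voxel indices by
#' the spacing (no rotation, origin at the first voxel).
#'
#' @param v a [volume_with_mask()]
#' @param affine 4x4 voxel-to-mm matrix (0-based voxel indices)
#' @return length-3 numeric (mm)
#' @export
tumor_center <- function(v, affine = NULL) {
  if (!any(v$mask)) stopf("mask is empty")
  if (is.null(affine)) {
    affine <- diag(c(v$spacing_mm, 1))
  }
  if (!is.matrix(affine) || any(dim(affine) != c(4, 4)))
    stopf("`affine` must be a 4x4 matrix")
  if (abs(det(affine[1:3, 1:3])) < 1e-12) stopf("singular affine")
  idx <- which(v$mask, arr.ind = TRUE) - 1 # 0-based voxel indices
  ctr_vox <- colMeans(idx)
  as.numeric(affine %*% c(ctr_vox, 1))[1:3]
}

#' Atlas-relative location features (464 values)
#'
#' For each atlas region center, the 3D displacement from the region center
#' to the tumor center (`delta = tumor - center`) and its Euclidean norm, in
#' atlas row order: `loc_<label>_{dx,dy,dz,norm}`.
#'
#' @param center tumor center, length-3 numeric (mm)
#' @param atlas data.frame with columns `label`, `x_mm`, `y_mm`, `z_mm`;
#'   must have 116 rows unless `allow_any_count = TRUE`
#' @param allow_any_count override the 116-region check
#' @return named numeric vector of length `4 * nrow(atlas)`
#' @export
location_features <- function(center, atlas, allow_any_count = FALSE) {
  stopifnot(length(center) == 3, all(is.finite(center)))
  need <- c("label", "x_mm", "y_mm", "z_mm")
  if (!all(need %in% names(atlas)))
    stopf("atlas must have columns %s", paste(need, collapse = ", "))
  if (anyDuplicated(atlas$label)) stopf("atlas labels must be unique")
  if (nrow(atlas) != 116 && !allow_any_count)
    stopf("atlas has %d regions, expected 116 (set allow_any_count to override)",
          nrow(atlas))
  dx <- center[1] - atlas$x_mm
  dy <- center[2] - atlas$y_mm
  dz <- center[3] - atlas$z_mm
  nrm <- sqrt(dx^2 + dy^2 + dz^2)
  out <- as.numeric(rbind(dx, dy, dz, nrm))
  names(out) <- as.vector(vapply(
    atlas$label, function(l) paste0("loc_", l, "_", c("dx", "dy", "dz", "norm")),
    character(4)))
  out
}
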