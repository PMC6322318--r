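#' Bundle a 3D intensity grid with an aligned binary tumor mask
#'
#' The unit every feature extractor consumes: a 3D array of intensities, a
#' logical array of identical shape marking the tumor, and the physical voxel
#' spacing in mm.
#'
#' @param intensities numeric 3D array
#' @param mask logical (or 0/1) 3D array of the same shape
#' @param spacing_mm length-3 positive numeric, voxel spacing in mm
#' @return an object of class `volume_with_mask`
#' @export
volume_with_mask <- function(intensities, mask,
                             spacing_mm = c(1, 1, 1)) {
  if (length(dim(intensities)) != 3) stopf("`intensities` must be a 3D array")
  mask <- array(as.logical(mask), dim(mask))
  if (!identical(dim(intensities), dim(mask)))
    stopf("`intensities` and `mask` must have identical dimensions")
  if (length(spacing_mm) != 3 || any(!is.finite(spacing_mm)) ||
      any(spacing_mm <= 0))
    stopf("`spacing_mm` must be 3 strictly positive reals")
  if (any(is.na(mask))) stopf("mask must not contain NA")
  structure(list(intensities = intensities, mask = mask,
                 spacing_mm = as.numeric(spacing_mm)),
            class = "volume_with_mask")
}

#' @export
print.volume_with_mask <- function(x, ...) {
  cat(sprintf("<volume_with_mask> grid %s, spacing %s mm, %d mask voxels\n",
              paste(dim(x$intensities), collapse = "x"),
              paste(signif(x$spacing_mm, 4), collapse = "x"),
              sum(x$mask)))
  invisible(x)
}

mask_voxel_count <- function(v) sum(v$mask)

voxel_volume_mm3 <- function(v) prod(v$spacing_mm)

in_mask <- function(v) v$intensities[v$mask]

#' Number of 6-connected components of a binary 3D mask
#' @param mask logical 3D array
#' @return integer component count
#' @export
count_components6 <- function(mask) {
  lab <- cpp_label6(as.logical(mask), dim(mask))
  max(lab)
}

#' Write a volume and its mask as NIfTI-1 files
#'
#' Spacing is carried in the NIfTI header (`pixdim`).
#'
#' @param v a [volume_with_mask()]
#' @param image_file,mask_file output paths (`.nii` or `.nii.gz`)
#' @return invisibly, the two paths
#' @export
write_volume_nifti <- function(v, image_file, mask_file) {
  img <- RNifti::asNifti(v$intensities)
  RNifti::pixdim(img) <- v$spacing_mm
  msk <- RNifti::asNifti(array(as.integer(v$mask), dim(v$mask)))
  RNifti::pixdim(msk) <- v$spacing_mm
  RNifti::writeNifti(img, image_file)
  RNifti::writeNifti(msk, mask_file)
  invisible(c(image_file, mask_file))
}

#' Read a volume and mask pair from NIfTI-1 files
#' @param image_file,mask_file input paths
#' @return a [volume_with_mask()]
#' @export
read_volume_nifti <- function(image_file, mask_file) {
  img <- RNifti::readNifti(image_file)
  msk <- RNifti::readNifti(mask_file)
  volume_with_mask(array(as.numeric(img), dim(img)),
                   array(as.numeric(msk) > 0.5, dim(msk)),
                   spacing_mm = RNifti::pixdim(img)[1:3])
}
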