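#' Names and category tags of the 555 image features
#'
#' @return data.frame with columns `feature` and `category`
#'   (intensity/shape/texture/wavelet), 555 rows in extraction order
#' @export
image_feature_bank <- function() {
  data.frame(
    feature = c(INTENSITY_FEATURE_NAMES, SHAPE_FEATURE_NAMES,
                TEXTURE_FEATURE_NAMES, wavelet_feature_names()),
    category = rep(c("intensity", "shape", "texture", "wavelet"),
                   c(21L, 15L, 39L, 480L)),
    stringsAsFactors = FALSE)
}

#' Extract the 555 image features from one volume + mask
#'
#' Concatenates, in fixed order, 21 first-order intensity, 15 shape, 39
#' texture and 480 wavelet features.
#'
#' @param v a [volume_with_mask()]
#' @param d a [discretization_spec()]
#' @param subbands optional precomputed [swt3()] sub-bands of `v$intensities`
#' @return named numeric vector of length 555
#' @export
extract_image_features <- function(v, d = discretization_spec(),
                                   subbands = NULL) {
  out <- c(intensity_features(v, d), shape_features(v),
           texture_features(v, d), wavelet_features(v, d, subbands))
  stopifnot(length(out) == 555L)
  out
}

#' Assemble the full 1021-column feature table for a cohort
#'
#' Per case: 464 atlas-relative location features, 2 clinical features
#' (`clin_gender_male` in {0,1}, `clin_age_years`), and the 555 image
#' features, in that column order.
#'
#' @param cohort list of cases from [generate_cohort()] (each with `volume`,
#'   `mask`, `gender`, `age_years`, `spacing_mm`)
#' @param atlas atlas-center table from [generate_atlas_centers()] (or read
#'   from a TSV): columns `label`, `x_mm`, `y_mm`, `z_mm`
#' @param d a [discretization_spec()]
#' @param verbose print one line per case
#' @return data.frame: `case_id` plus 1021 feature columns
#' @export
extract_cohort_features <- function(cohort, atlas,
                                    d = discretization_spec(),
                                    verbose = FALSE) {
  rows <- lapply(seq_along(cohort), function(i) {
    case <- cohort[[i]]
    v <- volume_with_mask(case$volume, case$mask, case$spacing_mm)
    loc <- location_features(tumor_center(v), atlas)
    clin <- c(clin_gender_male = as.numeric(case$gender == "male"),
              clin_age_years = case$age_years)
    img <- extract_image_features(v, d)
    if (verbose) message(sprintf("case %d/%d extracted", i, length(cohort)))
    c(loc, clin, img)
  })
  out <- as.data.frame(do.call(rbind, rows))
  data.frame(case_id = vapply(cohort, function(x) x$case_id, ""),
             out, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Category tag for every column of a full feature table
#' @param feature_names character vector of feature column names
#' @return character vector: location/clinical/intensity/shape/texture/wavelet
#' @export
feature_category <- function(feature_names) {
  bank <- image_feature_bank()
  out <- bank$category[match(feature_names, bank$feature)]
  out[startsWith(feature_names, "loc_")] <- "location"
  out[startsWith(feature_names, "clin_")] <- "clinical"
  out
}
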