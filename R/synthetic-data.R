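#' Configuration of a synthetic craniopharyngioma-like cohort
#'
#' The defaults emulate the statistical structure of a 44-patient
#' ACP/PCP cohort: class balance 26:18, in-plane spacing 0.488 mm with 1 mm
#' slices, tumors of a few thousand voxels, PCP tumors with a longer
#' intensity-texture correlation length and a mean-intensity offset, PCP
#' patients older on average, and mutation labels tied to pathology (PCP is
#' BRAF-mutant; ACP is CTNNB1-mutant except for a wild/wild leak of 10/44).
#'
#' @param n_cases cohort size (>= 10); default 44
#' @param class_balance fraction of ACP cases; default 26/44
#' @param image_shape grid size in voxels; default c(48, 48, 36)
#' @param spacing_mm voxel spacing; default c(0.488, 0.488, 1)
#' @param tumor_radius_range_vox ellipsoid semi-axis range in voxels
#' @param texture_contrast extra noise correlation length (voxels) of the
#'   PCP class relative to the ACP base of 1.0
#' @param intensity_shift PCP mean-intensity offset (16-bit units)
#' @param age_effect years subtracted from the ACP mean age relative to the
#'   PCP mean of 45
#' @param wild_leak fraction of ACP cases carrying neither mutation
#' @param seed integer seed; identical configs give bit-identical cohorts
#' @return an object of class `cohort_config`
#' @export
cohort_config <- function(n_cases = 44, class_balance = 26 / 44,
                          image_shape = c(48, 48, 36),
                          spacing_mm = c(0.488, 0.488, 1),
                          tumor_radius_range_vox = c(6, 11),
                          texture_contrast = 1.5, intensity_shift = 60,
                          age_effect = 15, wild_leak = 10 / 44, seed = 1) {
  n_cases <- check_count(n_cases, "n_cases", min = 10)
  class_balance <- check_fraction(class_balance, "class_balance")
  stopifnot(length(image_shape) == 3, all(image_shape >= 8),
            length(spacing_mm) == 3, all(spacing_mm > 0),
            length(tumor_radius_range_vox) == 2,
            all(tumor_radius_range_vox > 0),
            diff(tumor_radius_range_vox) >= 0,
            is.finite(texture_contrast), texture_contrast >= 0,
            is.finite(intensity_shift), is.finite(age_effect),
            wild_leak >= 0, wild_leak <= 1)
  structure(list(n_cases = n_cases, class_balance = class_balance,
                 image_shape = as.integer(image_shape),
                 spacing_mm = as.numeric(spacing_mm),
                 tumor_radius_range_vox = as.numeric(tumor_radius_range_vox),
                 texture_contrast = texture_contrast,
                 intensity_shift = intensity_shift,
                 age_effect = age_effect, wild_leak = wild_leak,
                 seed = check_count(seed, "seed", min = 0)),
            class = "cohort_config")
}

# one blobby (non-convex) tumor mask: an axis-aligned ellipsoid whose
# boundary is modulated by a smooth random field, reduced to the 6-connected
# component containing the center
synth_mask <- function(shape, radii, center, wobble = 0.15) {
  ax <- lapply(1:3, function(i) (seq_len(shape[i]) - center[i]) / radii[i])
  d2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`)
  pert <- gaussian_smooth3(array(rnorm(prod(shape)), shape), sigma = 2)
  pert <- pert / max(sd(pert), 1e-12)
  mask <- sqrt(d2) <= 1 + wobble * pert
  lab <- array(cpp_label6(as.logical(mask), shape), shape)
  ctr_lab <- lab[round(center[1]), round(center[2]), round(center[3])]
  if (ctr_lab == 0) { # wobble carved out the center: fall back to ellipsoid
    mask <- sqrt(d2) <= 1
    lab <- array(cpp_label6(as.logical(mask), shape), shape)
    ctr_lab <- lab[round(center[1]), round(center[2]), round(center[3])]
  }
  lab == ctr_lab
}

synth_case <- function(cfg, pathology, case_id) {
  shape <- cfg$image_shape
  rr <- cfg$tumor_radius_range_vox
  if ((1.2 * rr[2] + 3) * 2 > min(shape))
    stopf("tumor radius range %g-%g does not fit the %s grid",
          rr[1], rr[2], paste(shape, collapse = "x"))
  radii <- runif(3, rr[1], rr[2])
  center <- shape / 2 + runif(3, -2, 2)
  mask <- synth_mask(shape, radii, center)
  is_pcp <- pathology == "PCP"
  sigma_tex <- 1.0 + if (is_pcp) cfg$texture_contrast else 0
  grf <- gaussian_smooth3(array(rnorm(prod(shape)), shape), sigma_tex)
  grf <- grf / max(sd(grf), 1e-12)
  vol <- array(rnorm(prod(shape), 150, 30), shape)
  tumor_mean <- 600 + if (is_pcp) cfg$intensity_shift else 0
  vol[mask] <- tumor_mean + 120 * grf[mask] + rnorm(sum(mask), 0, 20)
  vol <- pmin(pmax(vol, 0), 65535)
  gender <- if (runif(1) < 29 / 44) "male" else "female"
  age <- if (is_pcp) rnorm(1, 45, 12) else rnorm(1, 45 - cfg$age_effect, 15)
  age <- min(max(age, 5), 80)
  if (is_pcp) {
    braf <- "mutant"; ctnnb1 <- "wild"
  } else {
    braf <- "wild"
    ctnnb1 <- if (runif(1) < cfg$wild_leak) "wild" else "mutant"
  }
  list(case_id = case_id, volume = vol, mask = mask,
       spacing_mm = cfg$spacing_mm, gender = gender, age_years = age,
       label_pathology = pathology, label_braf = braf,
       label_ctnnb1 = ctnnb1)
}

#' Generate a seeded synthetic cohort
#'
#' Each case carries a 3D intensity volume (16-bit range), a non-convex
#' single-component tumor mask, clinical covariates and the three labels.
#' Tumor interiors are smoothed Gaussian random fields whose correlation
#' length and mean differ by class; BRAF and CTNNB1 mutations are mutually
#' exclusive by construction.
#'
#' @param cfg a [cohort_config()]
#' @return list of cases (see [cohort_config()] for the generative model)
#' @export
generate_cohort <- function(cfg = cohort_config()) {
  stopifnot(inherits(cfg, "cohort_config"))
  n_acp <- round(cfg$class_balance * cfg$n_cases)
  pathology <- rep(c("ACP", "PCP"), c(n_acp, cfg$n_cases - n_acp))
  withr::with_seed(cfg$seed, {
    lapply(seq_len(cfg$n_cases), function(i) {
      synth_case(cfg, pathology[i], sprintf("case%03d", i))
    })
  })
}

#' Generate labeled synthetic atlas-region centers
#'
#' Uniformly placed, uniquely labeled 3D points inside a bounding box, as a
#' stand-in for a 116-region anatomical atlas centroid table.
#'
#' @param n_regions number of regions (default 116)
#' @param bounding_box 2 x 3 matrix: rows = (min, max), columns = x/y/z mm;
#'   default a brain-sized box
#' @param seed integer seed
#' @return data.frame: `label`, `x_mm`, `y_mm`, `z_mm`
#' @export
generate_atlas_centers <- function(n_regions = 116,
                                   bounding_box = rbind(c(-90, -126, -72),
                                                        c(90, 90, 108)),
                                   seed = 1) {
  n_regions <- check_count(n_regions, "n_regions")
  bb <- as.matrix(bounding_box)
  stopifnot(dim(bb) == c(2, 3), all(bb[2, ] >= bb[1, ]))
  withr::with_seed(seed, {
    data.frame(label = sprintf("AVOI_%03d", seq_len(n_regions)),
               x_mm = runif(n_regions, bb[1, 1], bb[2, 1]),
               y_mm = runif(n_regions, bb[1, 2], bb[2, 2]),
               z_mm = runif(n_regions, bb[1, 3], bb[2, 3]),
               stringsAsFactors = FALSE)
  })
}

#' Generate a feature table with a planted informative subset
#'
#' Noise columns are standard normal; informative columns differ between
#' the two balanced classes by `effect_size` standard deviations
#' (standardized mean difference).
#'
#' @param n_cases number of cases (split as evenly as possible)
#' @param n_features number of feature columns
#' @param informative integer indices of informative columns
#' @param effect_size nonnegative standardized mean difference
#' @param seed integer seed
#' @return list: `features` (data.frame `f0001`...) and `labels`
#'   (factor "neg"/"pos")
#' @export
generate_feature_table <- function(n_cases, n_features, informative = integer(),
                                   effect_size = 0, seed = 1) {
  n_cases <- check_count(n_cases, "n_cases", min = 2)
  n_features <- check_count(n_features, "n_features")
  if (length(informative) &&
      !all(informative %in% seq_len(n_features)))
    stopf("informative indices must lie in 1..n_features")
  if (!is.finite(effect_size) || effect_size < 0)
    stopf("effect_size must be a nonnegative real")
  labels <- factor(rep(c("neg", "pos"), length.out = n_cases),
                   levels = c("neg", "pos"))
  withr::with_seed(seed, {
    m <- matrix(rnorm(n_cases * n_features), n_cases, n_features)
    m[labels == "pos", informative] <- m[labels == "pos", informative] +
      effect_size
    colnames(m) <- sprintf("f%04d", seq_len(n_features))
    list(features = as.data.frame(m), labels = labels)
  })
}

#' Write a cohort to disk (NIfTI volumes/masks + covariate CSV)
#'
#' @param cohort a [generate_cohort()] result
#' @param dir output directory (created if needed)
#' @return invisibly, the covariate CSV path
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (case in cohort) {
    v <- volume_with_mask(case$volume, case$mask, case$spacing_mm)
    write_volume_nifti(v,
                       file.path(dir, paste0(case$case_id, "_img.nii.gz")),
                       file.path(dir, paste0(case$case_id, "_mask.nii.gz")))
  }
  cov <- data.frame(
    case_id = vapply(cohort, `[[`, "", "case_id"),
    gender = vapply(cohort, `[[`, "", "gender"),
    age = vapply(cohort, `[[`, 0, "age_years"),
    pathology = vapply(cohort, `[[`, "", "label_pathology"),
    braf = vapply(cohort, `[[`, "", "label_braf"),
    ctnnb1 = vapply(cohort, `[[`, "", "label_ctnnb1"),
    stringsAsFactors = FALSE)
  path <- file.path(dir, "covariates.csv")
  write.csv(cov, path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort written by [write_cohort()]
#' @param dir cohort directory
#' @return list of cases in covariate-file order
#' @export
read_cohort <- function(dir) {
  cov <- read.csv(file.path(dir, "covariates.csv"),
                  stringsAsFactors = FALSE)
  lapply(seq_len(nrow(cov)), function(i) {
    v <- read_volume_nifti(
      file.path(dir, paste0(cov$case_id[i], "_img.nii.gz")),
      file.path(dir, paste0(cov$case_id[i], "_mask.nii.gz")))
    list(case_id = cov$case_id[i], volume = v$intensities, mask = v$mask,
         spacing_mm = v$spacing_mm, gender = cov$gender[i],
         age_years = cov$age[i], label_pathology = cov$pathology[i],
         label_braf = cov$braf[i], label_ctnnb1 = cov$ctnnb1[i])
  })
}
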