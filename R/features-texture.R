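GLCM_FEATURE_NAMES <- c(
  "autocorrelation", "contrast", "correlation", "cluster_prominence",
  "cluster_shade", "cluster_tendency", "dissimilarity", "glcm_energy",
  "glcm_entropy", "homogeneity", "inverse_difference_moment",
  "maximum_probability", "sum_average", "sum_entropy", "sum_variance",
  "difference_entropy")

GLRLM_FEATURE_NAMES <- c(
  "short_run_emphasis", "long_run_emphasis", "gray_level_nonuniformity",
  "run_length_nonuniformity", "run_percentage",
  "low_gray_level_run_emphasis", "high_gray_level_run_emphasis",
  "short_run_low_gray_level_emphasis", "short_run_high_gray_level_emphasis",
  "long_run_low_gray_level_emphasis", "long_run_high_gray_level_emphasis",
  "gray_level_variance", "run_length_variance")

GLSZM_FEATURE_NAMES <- c(
  "small_zone_emphasis", "large_zone_emphasis",
  "zone_gray_level_nonuniformity", "zone_size_nonuniformity",
  "zone_percentage", "low_gray_level_zone_emphasis",
  "high_gray_level_zone_emphasis", "small_zone_low_gray_level_emphasis",
  "small_zone_high_gray_level_emphasis", "zone_size_variance")

TEXTURE_FEATURE_NAMES <- c(GLCM_FEATURE_NAMES, GLRLM_FEATURE_NAMES,
                           GLSZM_FEATURE_NAMES)

# The 13 unique 3D direction offsets at Chebyshev distance 1 (half of the
# 26-neighbourhood; the opposite offsets are covered by symmetry).
offsets13 <- function() {
  all <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  keep <- apply(all, 1, function(o) {
    nz <- o[o != 0]
    length(nz) > 0 && nz[length(nz)] > 0 # lexicographic half-space
  })
  unname(all[keep, , drop = FALSE])
}

#' Gray-level co-occurrence matrix for one displacement
#'
#' Symmetric (both voxel orders counted) and normalized to sum 1. Only pairs
#' with both voxels inside the ROI contribute.
#'
#' @param v a [volume_with_mask()]
#' @param d a [discretization_spec()]
#' @param offset integer length-3 voxel displacement
#' @return `n_levels` x `n_levels` matrix summing to 1 (or all-zero if the
#'   displacement yields no pairs)
#' @export
glcm_matrix <- function(v, d, offset) {
  lv <- discretize_roi(v$intensities, v$mask, d)
  m <- cpp_glcm_counts(as.integer(lv), dim(lv), as.integer(offset),
                       d$n_levels)
  s <- sum(m)
  if (s > 0) m / s else m
}

glcm_features_one <- function(p) {
  K <- nrow(p)
  i <- matrix(seq_len(K), K, K)
  j <- t(i)
  pi_ <- rowSums(p)
  mu_i <- sum(seq_len(K) * pi_)
  sd_i <- sqrt(sum((seq_len(K) - mu_i)^2 * pi_))
  # symmetric matrix: marginals equal
  corr <- if (sd_i > 0) sum((i - mu_i) * (j - mu_i) * p) / sd_i^2 else 0
  psum <- vapply(2:(2 * K), function(k) sum(p[i + j == k]), 0)
  pdiff <- vapply(0:(K - 1), function(k) sum(p[abs(i - j) == k]), 0)
  ent <- function(q) { q <- q[q > 0]; -sum(q * log2(q)) }
  sa <- sum((2:(2 * K)) * psum)
  c(autocorrelation = sum(i * j * p),
    contrast = sum((i - j)^2 * p),
    correlation = corr,
    cluster_prominence = sum((i + j - 2 * mu_i)^4 * p),
    cluster_shade = sum((i + j - 2 * mu_i)^3 * p),
    cluster_tendency = sum((i + j - 2 * mu_i)^2 * p),
    dissimilarity = sum(abs(i - j) * p),
    glcm_energy = sum(p^2),
    glcm_entropy = ent(p),
    homogeneity = sum(p / (1 + abs(i - j))),
    inverse_difference_moment = sum(p / (1 + (i - j)^2)),
    maximum_probability = max(p),
    sum_average = sa,
    sum_entropy = ent(psum),
    sum_variance = sum(((2:(2 * K)) - sa)^2 * psum),
    difference_entropy = ent(pdiff))
}

#' Gray-level run-length matrix for one direction
#'
#' Runs of equal discretized level along the direction; voxels outside the
#' ROI break runs. Rows are gray levels, columns run lengths (trailing
#' all-zero columns trimmed).
#'
#' @inheritParams glcm_matrix
#' @param direction integer length-3 step
#' @return counts matrix
#' @export
glrlm_matrix <- function(v, d, direction) {
  lv <- discretize_roi(v$intensities, v$mask, d)
  m <- cpp_glrlm_counts(as.integer(lv), dim(lv), as.integer(direction),
                        d$n_levels)
  last <- max(c(1L, which(colSums(m) > 0)))
  m[, seq_len(last), drop = FALSE]
}

glrlm_features_one <- function(r, n_vox) {
  nr <- sum(r)
  if (nr == 0) return(setNames(rep(0, 13), GLRLM_FEATURE_NAMES))
  p <- r / nr
  K <- nrow(r); L <- ncol(r)
  gl <- matrix(seq_len(K), K, L)
  rl <- matrix(seq_len(L), K, L, byrow = TRUE)
  pg <- rowSums(p)
  pl <- colSums(p)
  mu_g <- sum(seq_len(K) * pg)
  mu_l <- sum(seq_len(L) * pl)
  c(short_run_emphasis = sum(p / rl^2),
    long_run_emphasis = sum(p * rl^2),
    gray_level_nonuniformity = sum(rowSums(r)^2) / nr,
    run_length_nonuniformity = sum(colSums(r)^2) / nr,
    run_percentage = nr / n_vox,
    low_gray_level_run_emphasis = sum(p / gl^2),
    high_gray_level_run_emphasis = sum(p * gl^2),
    short_run_low_gray_level_emphasis = sum(p / (gl^2 * rl^2)),
    short_run_high_gray_level_emphasis = sum(p * gl^2 / rl^2),
    long_run_low_gray_level_emphasis = sum(p * rl^2 / gl^2),
    long_run_high_gray_level_emphasis = sum(p * gl^2 * rl^2),
    gray_level_variance = sum((gl - mu_g)^2 * p),
    run_length_variance = sum((rl - mu_l)^2 * p))
}

#' Gray-level size-zone table
#'
#' 26-connected zones of constant discretized level within the ROI.
#'
#' @inheritParams glcm_matrix
#' @return two-column matrix (level, size), one row per zone
#' @export
glszm_zones <- function(v, d) {
  lv <- discretize_roi(v$intensities, v$mask, d)
  cpp_glszm_zones(as.integer(lv), dim(lv))
}

glszm_features_one <- function(zones, n_vox) {
  nz <- nrow(zones)
  if (nz == 0) return(setNames(rep(0, 10), GLSZM_FEATURE_NAMES))
  gl <- zones[, 1]
  sz <- zones[, 2]
  p <- rep(1 / nz, nz)
  mu_s <- sum(sz * p)
  c(small_zone_emphasis = sum(p / sz^2),
    large_zone_emphasis = sum(p * sz^2),
    zone_gray_level_nonuniformity = sum(table(gl)^2) / nz,
    zone_size_nonuniformity = sum(table(sz)^2) / nz,
    zone_percentage = nz / n_vox,
    low_gray_level_zone_emphasis = sum(p / gl^2),
    high_gray_level_zone_emphasis = sum(p * gl^2),
    small_zone_low_gray_level_emphasis = sum(p / (gl^2 * sz^2)),
    small_zone_high_gray_level_emphasis = sum(p * gl^2 / sz^2),
    zone_size_variance = sum((sz - mu_s)^2 * p))
}

#' Texture features (39 values): GLCM, GLRLM and GLSZM statistics
#'
#' 16 co-occurrence features from symmetric margin-normalized matrices, and
#' 13 run-length features, each computed per direction over the 13 unique 3D
#' offsets at distance 1 and averaged over directions that produce at least
#' one pair/run; 10 size-zone features from 26-connected zones. All values
#' are finite for any ROI of >= 2 voxels (degenerate matrices fall back to
#' their single-run/zone definitions).
#'
#' @param v a [volume_with_mask()]
#' @param d a [discretization_spec()]
#' @return named numeric vector of length 39
#' @export
texture_features <- function(v, d = discretization_spec()) {
  if (mask_voxel_count(v) < 2) stopf("texture features need >= 2 ROI voxels")
  lv <- discretize_roi(v$intensities, v$mask, d)
  dims <- dim(lv)
  n_vox <- mask_voxel_count(v)
  offs <- offsets13()
  glcm_acc <- NULL; glcm_n <- 0
  glrlm_acc <- NULL; glrlm_n <- 0
  for (k in seq_len(nrow(offs))) {
    m <- cpp_glcm_counts(as.integer(lv), dims, as.integer(offs[k, ]),
                         d$n_levels)
    s <- sum(m)
    if (s > 0) {
      f <- glcm_features_one(m / s)
      glcm_acc <- if (is.null(glcm_acc)) f else glcm_acc + f
      glcm_n <- glcm_n + 1
    }
    r <- cpp_glrlm_counts(as.integer(lv), dims, as.integer(offs[k, ]),
                          d$n_levels)
    if (sum(r) > 0) {
      f <- glrlm_features_one(r, n_vox)
      glrlm_acc <- if (is.null(glrlm_acc)) f else glrlm_acc + f
      glrlm_n <- glrlm_n + 1
    }
  }
  glcm <- glcm_acc / glcm_n
  glrlm <- glrlm_acc / glrlm_n
  glszm <- glszm_features_one(cpp_glszm_zones(as.integer(lv), dims), n_vox)
  out <- c(glcm, glrlm, glszm)
  names(out) <- TEXTURE_FEATURE_NAMES
  out
}
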