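SHAPE_FEATURE_NAMES <- c(
  "volume_mm3", "surface_area_mm2", "surface_to_volume_ratio",
  "compactness1", "compactness2", "sphericity", "spherical_disproportion",
  "max_3d_diameter",
  "max_2d_diameter_axial", "max_2d_diameter_coronal", "max_2d_diameter_sagittal",
  "major_axis_length", "minor_axis_length", "least_axis_length",
  "elongation")

# Surface area (mm^2) of the mask boundary: marching-tetrahedra triangulation
# of the 0.5 level set of the Gaussian-smoothed (sigma 0.9 voxel) indicator.
# Smoothing places the interpolated vertices at sub-voxel positions, removing
# the constant directional overestimate of meshing raw binary data; validated
# against the analytic sphere area (see the methods vignette).
mask_surface_area <- function(mask, spacing_mm, sigma = 0.9) {
  f <- gaussian_smooth3(array(as.numeric(mask), dim(mask)), sigma)
  if (max(f) <= 0.5) {
    # ROI too thin for the smoothed level set (e.g. a single voxel or a
    # one-voxel slab): fall back to the exact exposed voxel-face area
    d <- dim(mask)
    face <- c(spacing_mm[2] * spacing_mm[3], spacing_mm[1] * spacing_mm[3],
              spacing_mm[1] * spacing_mm[2])
    area <- 0
    for (ax in 1:3) for (s in c(-1L, 1L)) {
      nb <- shift_padded(mask, ax, s)
      area <- area + sum(mask & !nb) * face[ax]
    }
    return(area)
  }
  cpp_surface_area(as.numeric(f), dim(mask), spacing_mm)
}

# mm coordinates of mask voxel centers, one row per voxel
mask_coords_mm <- function(mask, spacing_mm) {
  idx <- which(mask, arr.ind = TRUE)
  sweep(idx - 1, 2, spacing_mm, `*`)
}

# voxels with at least one out-of-mask 6-neighbour (grid boundary counts)
mask_surface_voxels <- function(mask) {
  d <- dim(mask)
  border <- array(FALSE, d)
  for (ax in 1:3) for (s in c(-1L, 1L)) {
    nb <- shift_padded(mask, ax, s)
    border <- border | (mask & !nb)
  }
  border
}

# neighbour values along one axis, FALSE/0 outside the grid
shift_padded <- function(a, ax, s, fill = FALSE) {
  d <- dim(a)
  out <- array(fill, d)
  n <- d[ax]
  src <- lapply(d, seq_len)
  dst <- lapply(d, seq_len)
  keep <- seq_len(n) + s
  ok <- keep >= 1L & keep <= n
  src[[ax]] <- keep[ok]
  dst[[ax]] <- which(ok)
  ref <- do.call(`[`, c(list(a), src))
  out <- do.call(`[<-`, c(list(out), dst, list(ref)))
  out
}

#' Morphological shape features (15 values)
#'
#' Volume by voxel counting, triangulated surface area, the derived
#' compactness/sphericity family, maximum 3D and per-plane 2D diameters, and
#' principal-axis lengths from the second moments of the voxel-center cloud
#' (axis length `4 * sqrt(eigenvalue)`, the full axis of the matching
#' ellipsoid). Shape ignores intensities entirely.
#'
#' @param v a [volume_with_mask()]; the mask must be one connected component
#' @return named numeric vector of length 15
#' @export
shape_features <- function(v) {
  mask <- v$mask
  if (!any(mask)) stopf("mask is empty")
  sp <- v$spacing_mm
  V <- sum(mask) * voxel_volume_mm3(v)
  A <- mask_surface_area(mask, sp)
  R <- (3 * V / (4 * pi))^(1 / 3)
  surf <- mask_surface_voxels(mask)
  pts <- mask_coords_mm(surf, sp)
  d3 <- if (nrow(pts) > 1) cpp_max_pairwise_dist(pts) else 0
  # per-plane max diameters: largest in-slice pairwise distance, over slices
  plane_diam <- function(slice_ax) {
    inplane <- setdiff(1:3, slice_ax)
    idx <- which(surf, arr.ind = TRUE)
    if (nrow(idx) == 0) return(0)
    best <- 0
    for (s in unique(idx[, slice_ax])) {
      rows <- idx[idx[, slice_ax] == s, inplane, drop = FALSE]
      if (nrow(rows) < 2) next
      p <- sweep(rows - 1, 2, sp[inplane], `*`)
      best <- max(best, cpp_max_pairwise_dist(p))
    }
    best
  }
  cc <- mask_coords_mm(mask, sp)
  ev <- if (nrow(cc) > 1) {
    eigen(stats::cov(cc) * (nrow(cc) - 1) / nrow(cc),
          symmetric = TRUE, only.values = TRUE)$values
  } else c(0, 0, 0)
  ev <- pmax(ev, 0)
  axes <- 4 * sqrt(ev) # descending: major, minor, least
  out <- c(
    V, A, A / V,
    V / (sqrt(pi) * A^1.5), 36 * pi * V^2 / A^3,
    pi^(1 / 3) * (6 * V)^(2 / 3) / A, A / (4 * pi * R^2),
    d3,
    plane_diam(3), plane_diam(2), plane_diam(1),
    axes[1], axes[2], axes[3],
    if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 0)
  names(out) <- SHAPE_FEATURE_NAMES
  out
}
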