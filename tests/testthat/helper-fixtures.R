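# Shared fixtures, built in code. Heavy objects are memoised per test run.

fixture_env <- new.env(parent = emptyenv())

# internal name banks, convenient in assertions
INTENSITY_FEATURE_NAMES <- cpradiomics:::INTENSITY_FEATURE_NAMES
SHAPE_FEATURE_NAMES <- cpradiomics:::SHAPE_FEATURE_NAMES
TEXTURE_FEATURE_NAMES <- cpradiomics:::TEXTURE_FEATURE_NAMES
WAVELET_BANDS <- cpradiomics:::WAVELET_BANDS

memo <- function(key, expr) {
  if (!exists(key, fixture_env)) assign(key, expr, fixture_env)
  get(key, fixture_env)
}

# digitized ball mask of radius r voxels, centered on a voxel
ball_mask <- function(r, margin = 5) {
  n <- 2 * r + 2 * margin + 1
  c0 <- (n + 1) / 2
  g <- expand.grid(x = seq_len(n), y = seq_len(n), z = seq_len(n))
  array((g$x - c0)^2 + (g$y - c0)^2 + (g$z - c0)^2 <= r^2, c(n, n, n))
}

# tiny single-blob volume: zero background, noisy tumor
toy_volume <- function(seed = 42, shape = c(20, 20, 12), r = 4) {
  withr::with_seed(seed, {
    c0 <- shape / 2
    g <- expand.grid(x = seq_len(shape[1]), y = seq_len(shape[2]),
                     z = seq_len(shape[3]))
    mask <- array((g$x - c0[1])^2 + (g$y - c0[2])^2 + (g$z - c0[3])^2 <= r^2,
                  shape)
    vol <- array(0, shape)
    vol[mask] <- 500 + rnorm(sum(mask), 0, 60)
    volume_with_mask(vol, mask, c(0.5, 0.5, 1))
  })
}

# small seeded cohort reused across files (generation is fast; extraction
# is what tests memoise individually)
tiny_cohort <- function(n = 10, seed = 7) {
  memo(sprintf("cohort_%d_%d", n, seed),
       generate_cohort(cohort_config(
         n_cases = n, image_shape = c(28, 28, 20),
         tumor_radius_range_vox = c(4, 5), seed = seed)))
}

informative_names <- function(k) sprintf("f%04d", seq_len(k))
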