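# Separable Gaussian smoothing of a 3D array, truncated kernel, replicated
# edges. Used for the surface mesh anti-aliasing and the synthetic
# correlated-texture fields; sigma is in voxels (may be 0 = identity).
gaussian_smooth3 <- function(a, sigma, radius = max(1L, ceiling(3 * sigma))) {
  if (sigma <= 0) return(a)
  k <- dnorm(seq(-radius, radius), sd = sigma)
  k <- k / sum(k)
  for (ax in 1:3) a <- filter_axis(a, k, ax, circular = FALSE)
  a
}

# Apply a 1D filter along one axis of a 3D array by shift-accumulate.
# circular = TRUE wraps (used by the wavelet transform); otherwise edges are
# replicated. Tap t of an L-tap kernel reads from offset t - ceiling(L/2).
filter_axis <- function(a, k, ax, circular) {
  d <- dim(a)
  n <- d[ax]
  out <- array(0, d)
  centre <- ceiling(length(k) / 2)
  idx <- lapply(d, seq_len)
  for (t in seq_along(k)) {
    off <- t - centre
    src <- idx
    s <- seq_len(n) + off
    s <- if (circular) ((s - 1) %% n) + 1 else pmin(pmax(s, 1L), n)
    src[[ax]] <- s
    out <- out + k[t] * do.call(`[`, c(list(a), src))
  }
  out
}
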