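`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a stage-specific RNG seed from a master seed
#'
#' Fans one master seed out to per-stage seeds by stable string hashing, so
#' that pipeline stages are individually reproducible without seed collisions.
#' The result is always in `[0, 2^31 - 2]`.
#'
#' @param seed master integer seed
#' @param ... stage labels (coerced to character) mixed into the hash
#' @return an integer seed
#' @export
derive_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  key <- paste(c(format(seed), vapply(list(...), format, "")), collapse = "/")
  h <- as.double(seed %% 2147483647L)
  for (cp in utf8ToInt(key)) h <- (h * 131 + cp) %% 2147483629
  as.integer(h)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)

check_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < min ||
      x != round(x))
    stopf("`%s` must be a single integer >= %d", name, min)
  as.integer(x)
}

check_fraction <- function(x, name, lo = 0, hi = 1) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= lo || x >= hi)
    stopf("`%s` must be a fraction in (%g, %g)", name, lo, hi)
  x
}

# short stable hex-ish hash of an R object (provenance stamping)
config_hash <- function(x) {
  key <- paste(deparse(x), collapse = " ")
  h <- 0
  for (cp in utf8ToInt(key)) h <- (h * 131 + cp) %% 2147483629
  sprintf("%08x", as.integer(h))
}
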