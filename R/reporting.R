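# ridge-penalized logistic IRLS (intercept unpenalized); fallback under
# complete separation, where the ML estimate diverges
ridge_logistic <- function(X, y, lambda = 1e-3, maxit = 200, tol = 1e-10) {
  X1 <- cbind(1, as.matrix(X))
  beta <- numeric(ncol(X1))
  pen <- diag(c(0, rep(lambda, ncol(X1) - 1)))
  for (it in seq_len(maxit)) {
    eta <- as.numeric(X1 %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    beta_new <- solve(crossprod(X1 * sqrt(w)) + pen, crossprod(X1, w * z))
    if (max(abs(beta_new - beta)) < tol) { beta <- beta_new; break }
    beta <- beta_new
  }
  as.numeric(beta)
}

# Point-scale construction shared by fit_nomogram: feature j spans
# 100 * |b_j| * range_j / max_k(|b_k| * range_k) points, anchored at the
# range endpoint that contributes least to the linear predictor. Invariant
# to rescaling all coefficients by a common factor.
nomogram_point_scale <- function(beta, lo, hi) {
  span <- abs(beta) * (hi - lo)
  S <- max(span)
  if (S <= 0) S <- 1 # all-zero model: flat scales
  ref <- ifelse(beta >= 0, lo, hi)
  list(table = data.frame(feature = names(beta), coefficient = unname(beta),
                          min = unname(lo), max = unname(hi),
                          ref = unname(ref),
                          max_points = unname(100 * span / S),
                          stringsAsFactors = FALSE),
       scale_unit = S)
}

#' Fit a logistic nomogram over selected (normalized) features
#'
#' Maximum-likelihood logistic regression on the selected features, with the
#' regression translated into a nomogram point system: feature j maps value
#' x to `100 * |b_j| * (x - ref_j) * sign(b_j) / S` points, where `ref_j` is
#' the observed range endpoint giving 0 points and
#' `S = max_k |b_k| * range_k`, so the most influential feature spans
#' exactly 0-100 points. Total points map back to probability through the
#' inverse logit of the reconstructed linear predictor. Under complete
#' separation the fit falls back to a lightly ridge-penalized likelihood and
#' is flagged.
#'
#' @param x data.frame of selected features (normalized to \[-1, 1\])
#' @param labels two-class label vector
#' @param positive label modeled as outcome 1
#' @return object of class `nomogram_model`: coefficients, per-feature
#'   observed ranges and point scales, the points-to-probability map, the
#'   per-case total points/probabilities, C-index, and `separated` flag
#' @export
fit_nomogram <- function(x, labels, positive) {
  x <- as.data.frame(x)
  y <- as.numeric(as_label_factor(labels, positive)) - 1
  if (min(table(y)) < 2) stopf("need >= 2 cases per class")
  sep <- FALSE
  g <- withCallingHandlers(
    glm(y ~ ., data = cbind(y = y, x), family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities|converge", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  separated <- sep || anyNA(coef(g)) || any(abs(coef(g)[-1]) > 15)
  beta <- if (separated) ridge_logistic(x, y) else as.numeric(coef(g))
  b0 <- beta[1]
  bj <- beta[-1]
  ps <- nomogram_point_scale(setNames(bj, names(x)),
                             vapply(x, min, 0), vapply(x, max, 0))
  point_scale <- ps$table
  S <- ps$scale_unit
  ref <- point_scale$ref
  points_of <- function(newx) {
    newx <- as.data.frame(newx)[names(x)]
    pts <- Map(function(col, b, r) 100 * b * (col - r) / S, newx, bj, ref)
    rowSums(as.data.frame(pts))
  }
  offset <- b0 + sum(bj * ref)
  prob_of_points <- function(p) plogis(offset + S * p / 100)
  total <- points_of(x)
  prob <- prob_of_points(total)
  structure(list(coefficients = c(intercept = b0, setNames(bj, names(x))),
                 point_scale = point_scale, scale_unit = S,
                 points_of = points_of, prob_of_points = prob_of_points,
                 total_points = total, probabilities = prob,
                 c_index = c_index(prob, y == 1),
                 separated = separated, positive = positive),
            class = "nomogram_model")
}

#' @export
print.nomogram_model <- function(x, ...) {
  cat(sprintf("<nomogram_model> positive = %s, C-index = %.3f%s\n",
              x$positive, x$c_index,
              if (x$separated) " (ridge fallback: separation)" else ""))
  print(x$point_scale, ...)
  invisible(x)
}

#' Harrell's C-index for binary outcomes
#'
#' Concordance probability of the predicted probabilities against the
#' outcome, ties counted 1/2; for binary outcomes this equals the ROC AUC.
#' Computed from midranks.
#'
#' @param probabilities numeric predictions
#' @param outcome logical (or 2-level) outcome
#' @return C-index in [0, 1]
#' @export
c_index <- function(probabilities, outcome) {
  pos <- as.logical(outcome)
  if (!any(pos) || all(pos)) stopf("both outcome classes must be present")
  r <- rank(probabilities) # midranks: ties counted 1/2
  n1 <- sum(pos)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * sum(!pos))
}

#' Mann-Whitney U test
#'
#' U is the number of (x, y) pairs with x > y (ties counted 1/2). The
#' two-sided p-value is exact (permutation distribution) when
#' `length(x) + length(y) <= 20` and there are no ties, and a tie-corrected
#' normal approximation otherwise.
#'
#' @param x,y numeric samples
#' @return list with `U` and `p`
#' @export
mann_whitney_u <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stopf("samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y)) <= 20 && !ties
  ht <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = FALSE))
  list(U = unname(ht$statistic), p = ht$p.value)
}

log_table_prob <- function(tab, lr, lc, ln) {
  lr + lc - ln - sum(lgamma(tab + 1))
}

#' Freeman-Halton (r x c) Fisher exact test
#'
#' Exact two-sided p-value by the probability-mass criterion: the sum of
#' hypergeometric probabilities of every margin-consistent table whose
#' probability does not exceed the observed table's (within relative
#' tolerance 1e-7), by full recursive enumeration. Tables with total count
#' above `max_total` fall back to Monte-Carlo sampling of the null
#' (Patefield's algorithm via [r2dtable()]) with the standard error reported
#' as an attribute.
#'
#' @param tab matrix of nonnegative integer counts, at least 2 x 2
#' @param max_total largest total for full enumeration (default 10000)
#' @param mc_draws Monte-Carlo sample size for the fallback
#' @param seed seed for the fallback sampler
#' @return two-sided p-value in [0, 1]
#' @export
fisher_exact_rxc <- function(tab, max_total = 10000, mc_draws = 100000,
                             seed = 1) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab))) stopf("counts must be nonnegative integers")
  if (nrow(tab) < 2 || ncol(tab) < 2) stopf("need at least a 2 x 2 table")
  rs <- rowSums(tab)
  cs <- colSums(tab)
  n <- sum(tab)
  lr <- sum(lgamma(rs + 1))
  lc <- sum(lgamma(cs + 1))
  ln <- lgamma(n + 1)
  lp_obs <- log_table_prob(tab, lr, lc, ln)
  cutoff <- lp_obs + 1e-7 # relative tolerance on the probability scale
  if (n > max_total) {
    draws <- withr::with_seed(seed, r2dtable(mc_draws, rs, cs))
    hits <- vapply(draws, function(m) log_table_prob(m, lr, lc, ln) <= cutoff,
                   TRUE)
    p <- mean(hits)
    attr(p, "mc_se") <- sqrt(p * (1 - p) / mc_draws)
    return(p)
  }
  nr <- nrow(tab); nc <- ncol(tab)
  total <- 0
  # Fill rows 1..nr-1 cell by cell; each row's last cell and the whole last
  # row are forced by the margins.
  recurse <- function(cur, r, c, row_left, col_left) {
    if (r == nr) {
      cur[nr, ] <- col_left
      lp <- log_table_prob(cur, lr, lc, ln)
      if (lp <= cutoff) total <<- total + exp(lp)
      return()
    }
    if (c == nc) {
      if (row_left > col_left[nc]) return()
      cur[r, nc] <- row_left
      col_left[nc] <- col_left[nc] - row_left
      recurse(cur, r + 1, 1, if (r + 1 < nr) rs[r + 1] else 0, col_left)
      return()
    }
    for (v in 0:min(row_left, col_left[c])) {
      cur[r, c] <- v
      cl <- col_left
      cl[c] <- cl[c] - v
      recurse(cur, r, c + 1, row_left - v, cl)
    }
  }
  recurse(matrix(0L, nr, nc), 1, 1, rs[1], cs)
  min(1, total)
}
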