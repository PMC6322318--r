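#' Configuration for the bootstrap importance ranking and forward selection
#'
#' @param n_bootstrap number of case resamples (default 100); each resample
#'   undergoes an internal `n_folds`-fold cross-validation, so the default
#'   produces `100 * 10 = 1000` ranking lists
#' @param n_folds folds per resample (default 10)
#' @param keep_fraction fraction of top-ranked features retained per fold
#'   list (default 0.25)
#' @param n_trees trees per forest (default 500)
#' @param sfs_max_k optional cap on how far down the ranking the forward
#'   selection walks; `Inf` (default) adds every ranked feature
#' @param seed integer master seed
#' @return an object of class `selection_config`
#' @export
selection_config <- function(n_bootstrap = 100, n_folds = 10,
                             keep_fraction = 0.25, n_trees = 500,
                             sfs_max_k = Inf, seed = 1) {
  cfg <- list(
    n_bootstrap = check_count(n_bootstrap, "n_bootstrap"),
    n_folds = check_count(n_folds, "n_folds", min = 2),
    keep_fraction = if (keep_fraction == 1) 1
                    else check_fraction(keep_fraction, "keep_fraction"),
    n_trees = check_count(n_trees, "n_trees"),
    sfs_max_k = sfs_max_k,
    seed = check_count(seed, "seed", min = 0))
  structure(cfg, class = "selection_config")
}

#' Normalize features to the [-1, 1] range
#'
#' `x -> 2 (x - min) / (max - min) - 1` per feature, with the training
#' (min, max) stored so the same mapping can be reapplied to new data (no
#' clipping: out-of-range values map outside \[-1, 1\]). Constant features
#' are dropped with a warning.
#'
#' @param x data.frame or matrix of numeric features
#' @return list: `features` (normalized data.frame) and `ranges`
#'   (data.frame feature/min/max)
#' @export
normalize_features <- function(x) {
  x <- as.data.frame(x)
  mins <- vapply(x, min, 0)
  maxs <- vapply(x, max, 0)
  const <- maxs <= mins
  if (any(const)) {
    warnf("dropping %d constant feature(s): %s", sum(const),
          paste(head(names(x)[const], 5), collapse = ", "))
    x <- x[!const]
    mins <- mins[!const]
    maxs <- maxs[!const]
  }
  norm <- as.data.frame(Map(function(col, lo, hi) 2 * (col - lo) / (hi - lo) - 1,
                            x, mins, maxs), check.names = FALSE,
                        optional = TRUE)
  names(norm) <- names(x)
  list(features = norm,
       ranges = data.frame(feature = names(x), min = unname(mins),
                           max = unname(maxs), stringsAsFactors = FALSE))
}

#' Reapply a stored normalization to new data
#' @param x data.frame of raw features (must contain every ranges$feature)
#' @param ranges the `ranges` element returned by [normalize_features()]
#' @return normalized data.frame with columns in `ranges` order
#' @export
apply_normalization <- function(x, ranges) {
  x <- as.data.frame(x)
  missing <- setdiff(ranges$feature, names(x))
  if (length(missing))
    stopf("missing feature column(s): %s", paste(missing, collapse = ", "))
  out <- Map(function(f, lo, hi) 2 * (x[[f]] - lo) / (hi - lo) - 1,
             ranges$feature, ranges$min, ranges$max)
  out <- as.data.frame(out, check.names = FALSE, optional = TRUE)
  names(out) <- ranges$feature
  out
}

#' Stage-2 selection: bootstrapped random-forest contribution ranking
#'
#' For each of `n_bootstrap` stratified case resamples (with replacement), a
#' stratified `n_folds`-fold split is drawn; in each fold a random forest is
#' fitted on the training part and features are ranked by mean impurity
#' decrease. The top `keep_fraction` of each fold's ranking contribute their
#' importance to a running sum (eliminated features contribute 0). Features
#' are returned in descending order of the accumulated contribution.
#'
#' @param x feature data.frame/matrix (cases x features)
#' @param labels two-class label vector
#' @param cfg a [selection_config()]
#' @param positive label treated as the positive class (any; ranking is
#'   class-symmetric)
#' @param case_ids case identifiers; partitioning is keyed by id so case
#'   order does not affect the result
#' @return data.frame (`feature`, `contribution`) sorted by descending
#'   contribution, with attribute `n_lists` = number of ranking lists
#' @export
stage2_rank <- function(x, labels, cfg = selection_config(),
                        positive = NULL, case_ids = NULL) {
  x <- as.data.frame(x)
  case_ids <- as.character(case_ids %||% sprintf("case%05d", seq_len(nrow(x))))
  ord <- order(case_ids)
  x <- x[ord, , drop = FALSE]
  labels <- as.character(labels)[ord]
  if (min(table(labels)) < 2) stopf("need >= 2 cases per class")
  y <- as_label_factor(labels, positive %||% sort(unique(labels))[2])
  p <- ncol(x)
  m_keep <- max(1L, ceiling(cfg$keep_fraction * p))
  contrib <- setNames(numeric(p), names(x))
  n_lists <- 0L
  for (b in seq_len(cfg$n_bootstrap)) {
    bs <- derive_seed(cfg$seed, "stage2", b)
    idx <- withr::with_seed(bs, unlist(lapply(
      split(seq_along(y), y),
      function(g) g[sample.int(length(g), length(g), replace = TRUE)])))
    fold <- stratified_folds(y[idx], sprintf("r%05d", seq_along(idx)),
                             cfg$n_folds, derive_seed(bs, "folds"))
    for (f in seq_len(cfg$n_folds)) {
      tr <- idx[fold != f]
      fit <- fit_forest(x[tr, , drop = FALSE], y[tr], cfg$n_trees,
                        derive_seed(bs, "fit", f), importance = "impurity")
      imp <- fit$variable.importance[names(x)]
      keep <- order(imp, decreasing = TRUE)[seq_len(m_keep)]
      contrib[keep] <- contrib[keep] + pmax(imp[keep], 0)
      n_lists <- n_lists + 1L
    }
  }
  out <- data.frame(feature = names(x), contribution = unname(contrib),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$contribution, seq_len(p)), ]
  rownames(out) <- NULL
  attr(out, "n_lists") <- n_lists
  out
}

#' Stage-3 selection: sequential forward selection over the ranking
#'
#' Walks the contribution ranking from the top, evaluating a random-forest
#' `n_folds`-fold cross-validated accuracy on the top-k features for
#' k = 1..K, and returns the smallest subset attaining the maximal accuracy
#' (parsimony tie-break). The folds are fixed across k so subsets are
#' compared on identical partitions.
#'
#' @inheritParams stage2_rank
#' @param ranked a [stage2_rank()] result (or any data.frame with a
#'   `feature` column in rank order)
#' @return list: `features` (chosen subset), `k`, `accuracy`, and
#'   `trace` (accuracy after adding each ranked feature)
#' @export
stage3_sfs <- function(x, labels, ranked, cfg = selection_config(),
                       positive = NULL, case_ids = NULL) {
  x <- as.data.frame(x)
  case_ids <- as.character(case_ids %||% sprintf("case%05d", seq_len(nrow(x))))
  ord <- order(case_ids)
  x <- x[ord, , drop = FALSE]
  labels <- as.character(labels)[ord]
  y <- as_label_factor(labels, positive %||% sort(unique(labels))[2])
  feats <- ranked$feature
  if (length(feats) == 0) stopf("empty ranking")
  K <- min(length(feats), cfg$sfs_max_k)
  fold <- stratified_folds(y, case_ids[ord], cfg$n_folds,
                           derive_seed(cfg$seed, "sfs-folds"))
  trace <- numeric(K)
  for (k in seq_len(K)) {
    cols <- feats[seq_len(k)]
    pred_pos <- logical(length(y))
    for (f in sort(unique(fold))) {
      tr <- which(fold != f)
      te <- which(fold == f)
      fit <- fit_forest(x[tr, cols, drop = FALSE], y[tr], cfg$n_trees,
                        derive_seed(cfg$seed, "sfs", k, f))
      pred_pos[te] <- vote_fraction(fit, x[te, cols, drop = FALSE]) > 0.5
    }
    trace[k] <- mean(pred_pos == (y == levels(y)[2]))
  }
  k_best <- which.max(trace) # first maximum = smallest subset
  list(features = feats[seq_len(k_best)], k = k_best,
       accuracy = trace[k_best], trace = trace)
}
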