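#' Cross-validated random-forest vote-fraction scores
#'
#' Stratified, seeded partition into `n_folds` near-equal folds; for each
#' fold a forest is fitted on the other folds and every validation case is
#' scored as the fraction of trees voting for the positive class, so each
#' case is scored exactly once by a model that never saw it.
#'
#' @param x feature data.frame (cases x selected features)
#' @param labels two-class label vector
#' @param positive the label counted as positive (scores near 1)
#' @param n_folds folds (default 10)
#' @param n_trees trees per forest (default 500)
#' @param seed integer seed
#' @param case_ids optional case identifiers (partition is keyed by id)
#' @return data.frame (`case_id`, `score`, `fold`, `label`) in input case
#'   order, with attribute `fold_train`: per fold, the case ids the fold's
#'   model was trained on (leakage bookkeeping)
#' @export
cv_scores <- function(x, labels, positive, n_folds = 10, n_trees = 500,
                      seed = 1, case_ids = NULL) {
  x <- as.data.frame(x)
  n <- nrow(x)
  if (n < n_folds) stopf("need at least n_folds cases")
  case_ids <- as.character(case_ids %||% sprintf("case%05d", seq_len(n)))
  y <- as_label_factor(labels, positive)
  if (min(table(y)) < 1) stopf("both classes must be present")
  fold <- stratified_folds(y, case_ids, n_folds, derive_seed(seed, "cv-folds"))
  score <- numeric(n)
  fold_train <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    tr <- which(fold != f)
    te <- which(fold == f)
    if (length(unique(y[tr])) < 2) stopf("training part lost a class")
    fit <- fit_forest(x[tr, , drop = FALSE], y[tr], n_trees,
                      derive_seed(seed, "cv-fit", f))
    if (length(te)) score[te] <- vote_fraction(fit, x[te, , drop = FALSE])
    fold_train[[f]] <- case_ids[tr]
  }
  out <- data.frame(case_id = case_ids, score = score, fold = fold,
                    label = as.character(labels), stringsAsFactors = FALSE)
  attr(out, "fold_train") <- fold_train
  attr(out, "positive") <- positive
  out
}

#' Threshold vote scores into class predictions
#'
#' A case is called positive iff its score is strictly above the threshold
#' (a score of exactly 0.5 is negative).
#'
#' @param scores a [cv_scores()] data.frame (or numeric vector)
#' @param threshold default 0.5
#' @return logical vector: positive prediction per case
#' @export
classify <- function(scores, threshold = 0.5) {
  s <- if (is.data.frame(scores)) scores$score else scores
  s > threshold
}

#' Trapezoidal area under the ROC curve
#'
#' Computed from the score-ranked ROC with proper tie grouping; equal to the
#' tie-corrected pairwise concordance probability.
#'
#' @param score numeric scores
#' @param is_pos logical truth
#' @return AUC in [0, 1]
#' @export
auc_trapezoid <- function(score, is_pos) {
  if (!any(is_pos) || all(is_pos)) stopf("both classes must be present")
  ths <- sort(unique(score), decreasing = TRUE)
  tp <- vapply(ths, function(t) sum(score >= t & is_pos), 0)
  fp <- vapply(ths, function(t) sum(score >= t & !is_pos), 0)
  tpr <- c(0, tp / sum(is_pos), 1)
  fpr <- c(0, fp / sum(!is_pos), 1)
  sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
}

#' Confusion-matrix and ROC metrics for scored cases
#'
#' AUC from the trapezoidal ROC of the pooled cross-validation scores;
#' ACC/SENS/SPEC/PPV/NPV/MCC from the thresholded confusion matrix. MCC is
#' defined as 0 when any marginal factor of its denominator is 0.
#'
#' @param scores a [cv_scores()] data.frame
#' @param predictions logical predictions (default: [classify()] at 0.5)
#' @param oob optional out-of-bag score to carry into the report
#' @return named list: auc, acc, sens, spec, ppv, npv, mcc, oob
#' @export
compute_metrics <- function(scores, predictions = classify(scores),
                            oob = NA_real_) {
  pos <- attr(scores, "positive")
  truth <- scores$label == pos
  if (!any(truth) || all(truth)) stopf("both classes must be present")
  tp <- sum(predictions & truth)
  tn <- sum(!predictions & !truth)
  fp <- sum(predictions & !truth)
  fn <- sum(!predictions & truth)
  den <- prod(sqrt(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  list(auc = auc_trapezoid(scores$score, truth),
       acc = (tp + tn) / length(truth),
       sens = tp / (tp + fn),
       spec = tn / (tn + fp),
       ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
       mcc = if (den > 0) (tp * tn - fp * fn) / den else 0,
       oob = oob)
}

#' Out-of-bag generalization accuracy
#'
#' One forest fitted on all cases; each case is predicted by the majority
#' vote of the trees whose bootstrap sample excluded it. Cases never
#' out-of-bag (rare) are excluded with a warning.
#'
#' @inheritParams cv_scores
#' @return OOB accuracy in [0, 1]
#' @export
oob_score <- function(x, labels, positive, n_trees = 500, seed = 1) {
  y <- as_label_factor(labels, positive)
  if (min(table(y)) < 2) stopf("need >= 2 cases per class")
  fit <- fit_forest(as.data.frame(x), y, n_trees, derive_seed(seed, "oob"))
  pred <- fit$predictions
  if (anyNA(pred)) {
    warnf("%d case(s) never out-of-bag excluded from OOB score", sum(is.na(pred)))
  }
  mean(pred == y, na.rm = TRUE)
}

#' Evaluate a feature subset end to end
#'
#' Runs [cv_scores()], thresholds at 0.5, and assembles the full metrics
#' report including the all-cases OOB score.
#'
#' @inheritParams cv_scores
#' @return list: `scores` (data.frame) and `metrics` (8-key list)
#' @export
evaluate_model <- function(x, labels, positive, n_folds = 10, n_trees = 500,
                           seed = 1, case_ids = NULL) {
  sc <- cv_scores(x, labels, positive, n_folds, n_trees, seed, case_ids)
  oob <- oob_score(x, labels, positive, n_trees, seed)
  list(scores = sc, metrics = compute_metrics(sc, classify(sc), oob = oob))
}

#' Evaluate a frozen feature subset on an extended cohort
#'
#' The extension protocol: features selected on the main cohort are applied
#' to the extended cohort directly, skipping re-selection; scoring and
#' metrics are as in [evaluate_model()].
#'
#' @param selected character vector of feature names chosen on the main
#'   cohort
#' @param x extended feature data.frame (must contain every selected column)
#' @inheritParams cv_scores
#' @return list: `scores` and `metrics`
#' @export
evaluate_extended <- function(selected, x, labels, positive, n_folds = 10,
                              n_trees = 500, seed = 1, case_ids = NULL) {
  x <- as.data.frame(x)
  missing <- setdiff(selected, names(x))
  if (length(missing))
    stopf("extended table lacks selected feature(s): %s",
          paste(missing, collapse = ", "))
  evaluate_model(x[selected], labels, positive, n_folds, n_trees, seed,
                 case_ids)
}
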