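# Random-forest backend: ranger, single-threaded for reproducibility.
# Labels are handled as factors whose second level is the positive class.

as_label_factor <- function(labels, positive) {
  labels <- as.character(labels)
  neg <- setdiff(unique(labels), positive)
  if (length(neg) != 1) stopf("labels must have exactly 2 classes")
  factor(labels, levels = c(neg, positive))
}

fit_forest <- function(x, y, n_trees, seed, importance = "none") {
  ranger::ranger(x = as.data.frame(x), y = y,
                 num.trees = n_trees, seed = seed,
                 num.threads = 1, importance = importance,
                 respect.unordered.factors = TRUE)
}

# positive-vote fraction per row of newx: proportion of trees predicting
# the positive class (second factor level)
vote_fraction <- function(fit, newx, positive_level = 2L) {
  pr <- predict(fit, data = as.data.frame(newx), predict.all = TRUE,
                num.threads = 1)$predictions
  rowMeans(pr == positive_level)
}

# Stratified fold assignment keyed by case id: the partition depends only on
# the set of ids (and the labels), not on the order the cases arrive in.
stratified_folds <- function(labels, case_ids, n_folds, seed) {
  ord <- order(as.character(case_ids))
  labs <- as.character(labels)[ord]
  fold <- integer(length(labs))
  withr::with_seed(seed, {
    at <- 0L # running round-robin position, shared across classes so
             # overall fold sizes stay within 1 of each other
    for (cl in sort(unique(labs))) {
      members <- which(labs == cl)
      members <- members[sample.int(length(members))]
      fold[members] <- ((at + seq_along(members) - 1L) %% n_folds) + 1L
      at <- at + length(members)
    }
  })
  out <- integer(length(labs))
  out[ord] <- fold
  out
}
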