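#!/usr/bin/env Rscript
# Stages 2-3 of feature selection, per task: normalize the surviving
# features to [-1, 1], rank them by summed impurity contribution over
# 100 bootstrap x 10-fold random forests (1000 ranking lists, top 25%
# retained per list), then walk the ranking with sequential forward
# selection under 10-fold CV accuracy.

library(cpradiomics)

feats <- read.csv("results/features.csv", check.names = FALSE)
icc_rep <- read.csv("results/icc_report.csv")
cov <- read.csv("results/cohort/covariates.csv")

fx <- feats[setdiff(names(feats), "case_id")]
keep <- names(fx)[feature_category(names(fx)) %in% c("location", "clinical") |
                    names(fx) %in% icc_rep$feature[icc_rep$pass]]
cat(sprintf("%d features enter selection (location + clinical + robust)\n",
            length(keep)))
norm <- suppressWarnings(normalize_features(fx[keep]))
write.csv(norm$ranges, "results/normalization_ranges.csv", row.names = FALSE)

labels_of <- list(pathology = cov$pathology, braf = cov$braf,
                  ctnnb1 = cov$ctnnb1)
positive_of <- c(pathology = "ACP", braf = "mutant", ctnnb1 = "mutant")

for (task in names(labels_of)) {
  cfg <- selection_config(seed = derive_seed(20260926, "select", task))
  t0 <- Sys.time()
  rk <- stage2_rank(norm$features, labels_of[[task]], cfg,
                    positive = positive_of[task], case_ids = feats$case_id)
  sfs <- stage3_sfs(norm$features, labels_of[[task]], rk, cfg,
                    positive = positive_of[task], case_ids = feats$case_id)
  cat(sprintf("[%s] %d lists, chose %d features (CV acc %.3f) in %.1f min: %s\n",
              task, attr(rk, "n_lists"), sfs$k, sfs$accuracy,
              as.numeric(difftime(Sys.time(), t0, units = "mins")),
              paste(sfs$features, collapse = ", ")))
  write.csv(rk, sprintf("results/ranked_%s.csv", task), row.names = FALSE)
  jsonlite::write_json(
    list(task = task, features = sfs$features, k = sfs$k,
         accuracy = sfs$accuracy, trace = sfs$trace),
    sprintf("results/selected_%s.json", task), auto_unbox = TRUE, digits = NA)
}
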