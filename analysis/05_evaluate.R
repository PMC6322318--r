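#!/usr/bin/env Rscript
# Outer random-forest evaluation of each task's selected subset: pooled
# 10-fold CV vote-fraction scores, ROC/threshold metrics at the 0.5 cut,
# and the all-cases OOB generalization score.

library(cpradiomics)

feats <- read.csv("results/features.csv", check.names = FALSE)
cov <- read.csv("results/cohort/covariates.csv")
ranges <- read.csv("results/normalization_ranges.csv")
norm <- apply_normalization(feats[setdiff(names(feats), "case_id")], ranges)

labels_of <- list(pathology = cov$pathology, braf = cov$braf,
                  ctnnb1 = cov$ctnnb1)
positive_of <- c(pathology = "ACP", braf = "mutant", ctnnb1 = "mutant")

summary_rows <- list()
for (task in names(labels_of)) {
  sel <- jsonlite::read_json(sprintf("results/selected_%s.json", task),
                             simplifyVector = TRUE)
  ev <- evaluate_model(norm[sel$features], labels_of[[task]],
                       positive_of[task],
                       seed = derive_seed(20260926, "eval", task),
                       case_ids = feats$case_id)
  jsonlite::write_json(ev$metrics, sprintf("results/metrics_%s.json", task),
                       auto_unbox = TRUE, digits = NA)
  write.csv(ev$scores, sprintf("results/scores_%s.csv", task),
            row.names = FALSE)
  summary_rows[[task]] <- data.frame(task = task, n_features = sel$k,
                                     as.data.frame(ev$metrics))
  cat(sprintf("[%s] AUC %.3f ACC %.3f SENS %.3f SPEC %.3f MCC %.3f OOB %.3f\n",
              task, ev$metrics$auc, ev$metrics$acc, ev$metrics$sens,
              ev$metrics$spec, ev$metrics$mcc, ev$metrics$oob))
}
write.csv(do.call(rbind, summary_rows), "results/metrics_summary.csv",
          row.names = FALSE)
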