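#!/usr/bin/env Rscript
# Extensional-dataset mode: enlarge the main cohort with 12 additional
# simulated cases (standing in for the recurrent/treated patients), reuse
# the feature subsets selected on the main cohort, and re-evaluate without
# any re-selection.

library(cpradiomics)

main <- read_cohort("results/cohort")
extra_cfg <- cohort_config(n_cases = 12, class_balance = 0.5,
                           seed = derive_seed(20260926, "extension"))
extra <- generate_cohort(extra_cfg)
for (i in seq_along(extra)) extra[[i]]$case_id <- sprintf("ext%03d", i)
cohort <- c(main, extra)

atlas <- read.delim("results/cohort/atlas_centers.tsv")
tab <- extract_cohort_features(cohort, atlas)
fx <- tab[setdiff(names(tab), "case_id")]
norm <- suppressWarnings(normalize_features(fx))

labels_of <- list(
  pathology = vapply(cohort, `[[`, "", "label_pathology"),
  braf = vapply(cohort, `[[`, "", "label_braf"),
  ctnnb1 = vapply(cohort, `[[`, "", "label_ctnnb1"))
positive_of <- c(pathology = "ACP", braf = "mutant", ctnnb1 = "mutant")

for (task in names(labels_of)) {
  sel <- jsonlite::read_json(sprintf("results/selected_%s.json", task),
                             simplifyVector = TRUE)
  ev <- evaluate_extended(sel$features, norm$features, labels_of[[task]],
                          positive_of[task],
                          seed = derive_seed(20260926, "ext-eval", task),
                          case_ids = tab$case_id)
  jsonlite::write_json(ev$metrics,
                       sprintf("results/metrics_extended_%s.json", task),
                       auto_unbox = TRUE, digits = NA)
  cat(sprintf("[extended %s] n = %d, AUC %.3f ACC %.3f OOB %.3f\n",
              task, nrow(norm$features), ev$metrics$auc, ev$metrics$acc,
              ev$metrics$oob))
}
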