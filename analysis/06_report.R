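#!/usr/bin/env Rscript
# Reporting: per-task logistic nomograms with 0-100 point scales and
# Harrell's C-index; cohort-table statistics (Mann-Whitney U for age,
# Freeman-Halton Fisher exact for gender/pathology by mutation group);
# violin and ROC source data, with figures if ggplot2 is available.

library(cpradiomics)

feats <- read.csv("results/features.csv", check.names = FALSE)
cov <- read.csv("results/cohort/covariates.csv")
ranges <- read.csv("results/normalization_ranges.csv")
norm <- apply_normalization(feats[setdiff(names(feats), "case_id")], ranges)

labels_of <- list(pathology = cov$pathology, braf = cov$braf,
                  ctnnb1 = cov$ctnnb1)
positive_of <- c(pathology = "ACP", braf = "mutant", ctnnb1 = "mutant")

dir.create("results/report", showWarnings = FALSE)
violin <- list()
for (task in names(labels_of)) {
  sel <- jsonlite::read_json(sprintf("results/selected_%s.json", task),
                             simplifyVector = TRUE)
  nm <- fit_nomogram(norm[sel$features], labels_of[[task]],
                     positive_of[task])
  jsonlite::write_json(
    list(task = task, coefficients = as.list(nm$coefficients),
         point_scale = nm$point_scale, c_index = nm$c_index,
         separated = nm$separated),
    sprintf("results/report/nomogram_%s.json", task),
    auto_unbox = TRUE, digits = NA)
  cat(sprintf("[%s] nomogram C-index %.3f%s\n", task, nm$c_index,
              if (nm$separated) " (ridge fallback)" else ""))
  for (f in sel$features) {
    mw <- mann_whitney_u(norm[[f]][labels_of[[task]] == positive_of[task]],
                         norm[[f]][labels_of[[task]] != positive_of[task]])
    violin[[length(violin) + 1]] <- data.frame(
      task = task, feature = f, value = norm[[f]],
      group = labels_of[[task]], p = mw$p)
  }
}
violin <- do.call(rbind, violin)
write.csv(violin, "results/report/violin_data.csv", row.names = FALSE)

# cohort table tests on the simulated cohort
grp <- ifelse(cov$braf == "mutant", "BRAF",
              ifelse(cov$ctnnb1 == "mutant", "CTNNB1", "ND"))
p_gender <- fisher_exact_rxc(table(grp, cov$gender))
p_path <- fisher_exact_rxc(table(grp, cov$pathology))
cat(sprintf("simulated cohort: gender x group p = %.3f, pathology x group p = %.3g\n",
            p_gender, p_path))
# the published cohort table reproduces its printed p-value
pub <- matrix(c(9, 14, 6, 3, 8, 4), nrow = 3,
              dimnames = list(c("BRAF", "CTNNB1", "ND"), c("male", "female")))
cat(sprintf("published gender x group table: p = %.3f\n",
            fisher_exact_rxc(pub)))

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  gv <- ggplot(violin, aes(group, value, fill = group)) +
    geom_violin() + facet_wrap(task ~ feature, scales = "free") +
    theme_minimal() + theme(legend.position = "none")
  ggsave("results/report/violin.pdf", gv, width = 10, height = 7)
  rocs <- do.call(rbind, lapply(names(labels_of), function(task) {
    sc <- read.csv(sprintf("results/scores_%s.csv", task))
    pos <- sc$label == positive_of[task]
    th <- sort(unique(c(0, sc$score, 1)), decreasing = TRUE)
    data.frame(task = task,
               fpr = vapply(th, function(t) mean(sc$score[!pos] >= t), 0),
               tpr = vapply(th, function(t) mean(sc$score[pos] >= t), 0))
  }))
  write.csv(rocs, "results/report/roc_data.csv", row.names = FALSE)
  gr <- ggplot(rocs, aes(fpr, tpr, colour = task)) +
    geom_step() + geom_abline(linetype = 3) + coord_equal() +
    theme_minimal()
  ggsave("results/report/roc.pdf", gr, width = 6, height = 5)
}
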