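#!/usr/bin/env Rscript
# Simulate the study cohort: 44 cases (26 ACP / 18 PCP), T1-like volumes
# with blobby tumor masks, class-linked texture/intensity/age contrasts,
# mutually exclusive BRAF/CTNNB1 labels, plus a 116-region atlas-center
# table. Everything is seeded; rerunning reproduces the same cohort.

library(cpradiomics)

out <- "results/cohort"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- cohort_config(seed = 20260926)
cohort <- generate_cohort(cfg)
write_cohort(cohort, out)

atlas <- generate_atlas_centers(seed = derive_seed(cfg$seed, "atlas"))
write.table(atlas, file.path(out, "atlas_centers.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)

cov <- read.csv(file.path(out, "covariates.csv"))
cat(sprintf("wrote %d cases to %s\n", nrow(cov), out))
print(table(cov$pathology, cov$braf, dnn = c("pathology", "BRAF")))
print(table(cov$pathology, cov$ctnnb1, dnn = c("pathology", "CTNNB1")))
cat(sprintf("mask sizes: %s voxels\n",
            paste(range(vapply(cohort, function(k) sum(k$mask), 0)),
                  collapse = "-")))
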