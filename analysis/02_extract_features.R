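#!/usr/bin/env Rscript
# Extract the 1021-feature table for the simulated cohort: 464 atlas-
# relative location features, 2 clinical covariates and 555 image features
# (21 intensity, 15 shape, 39 texture, 480 wavelet) per case.

library(cpradiomics)

cohort <- read_cohort("results/cohort")
atlas <- read.delim("results/cohort/atlas_centers.tsv")

t0 <- Sys.time()
tab <- extract_cohort_features(cohort, atlas, verbose = TRUE)
cat(sprintf("extracted %d x %d features in %.1f s\n",
            nrow(tab), ncol(tab) - 1,
            as.numeric(difftime(Sys.time(), t0, units = "secs"))))

write.csv(tab, "results/features.csv", row.names = FALSE)
print(table(feature_category(setdiff(names(tab), "case_id"))))
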