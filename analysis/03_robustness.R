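#!/usr/bin/env Rscript
# Stage-1 selection: perturb every tumor mask by the 8 scenarios
# (translations, 1/5-degree rotations, their compositions, dilation,
# erosion), recompute the 555 image features per variant, and keep the
# features whose ICC(1,1) across the 9 variants exceeds 0.8.

library(cpradiomics)

cohort <- read_cohort("results/cohort")
cases <- lapply(cohort, function(k)
  volume_with_mask(k$volume, k$mask, k$spacing_mm))

t0 <- Sys.time()
report <- robustness_screen(cases)
cat(sprintf("screened %d features on %d cases in %.1f min\n",
            nrow(report), length(cases),
            as.numeric(difftime(Sys.time(), t0, units = "mins"))))

write.csv(report, "results/icc_report.csv", row.names = FALSE)
cat(sprintf("robust (ICC > 0.8): %d / %d image features\n",
            sum(report$pass), nrow(report)))
print(aggregate(pass ~ category, report, mean))
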