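#!/usr/bin/env Rscript
# Step 2: cohort description tables.
#
# Regenerates the clinical and imaging group-comparison tables (severe vs
# normal-moderate outcome): n (%), mean (SD) or median (range) per group,
# Fisher's exact / Mann-Whitney p-values, stars at p < 0.05.

suppressPackageStartupMessages(library(ndiscore))

coh <- load_cohort("results/cohort.csv")
rep <- cohort_report(coh, seed = 2018L)

write.csv(rep$clinical, "results/table_clinical.csv", row.names = FALSE)
write.csv(rep$imaging, "results/table_imaging.csv", row.names = FALSE)

cat("Clinical characteristics by outcome group:\n")
print(rep$clinical, right = FALSE)
cat("\nImaging characteristics by outcome group:\n")
print(rep$imaging, right = FALSE)
cat("\nWrote results/table_clinical.csv and results/table_imaging.csv\n")
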