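#!/usr/bin/env Rscript
# Step 1: draw the working cohort.
#
# We have no access to the original 154-infant cohort, so every downstream
# analysis runs on a seeded synthetic cohort whose group-conditional
# structure matches the published clinical and imaging tables. The cohort
# is written to results/cohort.csv and reloaded (and therefore revalidated)
# by each later step.

suppressPackageStartupMessages(library(ndiscore))

seed <- 2018L
coh <- simulate_cohort(synthetic_config(), seed = seed)

dir.create("results", showWarnings = FALSE)
write_cohort(coh, "results/cohort.csv")

cat("Simulated cohort (seed", seed, "):\n")
print(coh[0, ])
cat(sprintf("  n = %d infants, %d (%d%%) with severe impairment\n",
            nrow(coh), sum(coh$severe), pct(sum(coh$severe), nrow(coh))))
cat(sprintf("  gestational age: severe %.1f wk, non-severe %.1f wk\n",
            mean(coh$gestational_age[coh$severe]),
            mean(coh$gestational_age[!coh$severe])))
s <- cohort_scores(coh)
cat(sprintf("  MRI score (final weights): severe %.1f +/- %.1f, non-severe %.1f +/- %.1f\n",
            mean(s[coh$severe]), sd(s[coh$severe]),
            mean(s[!coh$severe]), sd(s[!coh$severe])))
cat("Wrote results/cohort.csv\n")
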