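#!/usr/bin/env Rscript
# Step 3: the MRI injury score and its weighting.
#
# Scores every infant with the published final weight table, reports the
# per-group score distribution and the operating characteristics of the
# published >8 threshold, and runs the greedy weight learner from the
# equal-weight baseline on this cohort. On noisy cohorts the strict
# acceptance rule (sensitivity strictly up, specificity not down) is
# conservative and typically retains the baseline; the full proposal trace
# is written so every accept/reject decision can be inspected.

suppressPackageStartupMessages(library(ndiscore))

coh <- load_cohort("results/cohort.csv")
scores <- cohort_scores(coh, final_weights())

cat("Final weight table:\n")
print(final_weights())
cat(sprintf("\nScore distribution: severe %.1f +/- %.1f, non-severe %.1f +/- %.1f\n",
            mean(scores[coh$severe]), sd(scores[coh$severe]),
            mean(scores[!coh$severe]), sd(scores[!coh$severe])))

m8 <- operating_metrics(scores, coh$severe, 8)
cat("\nOperating characteristics of the score-threshold rule (> 8):\n")
print(m8)
thr <- best_threshold(scores, coh$severe)
cat(sprintf("Youden-optimal integer threshold on this cohort: > %d\n", thr))
print(operating_metrics(scores, coh$severe, thr))

res <- learn_weights(coh, search_config())
cat("\nGreedy learner from the equal-weight baseline:\n")
cat(sprintf("  %d proposals, %d accepted\n", nrow(res$trace),
            sum(res$trace$accepted)))
print(res$weights)

jsonlite::write_json(
  list(seed = 2018L,
       weights = as.list(unclass(res$weights)),
       threshold = res$threshold,
       sensitivity = res$sensitivity, specificity = res$specificity),
  "results/learned_weights.json", auto_unbox = TRUE, digits = NA)
write.csv(res$trace, "results/weight_search_trace.csv", row.names = FALSE)
jsonlite::write_json(
  list(seed = 2018L, threshold = 8,
       sensitivity = m8$sensitivity, specificity = m8$specificity,
       ppv = m8$ppv, npv = m8$npv),
  "results/score_threshold_metrics.json", auto_unbox = TRUE, digits = NA)
cat("Wrote results/learned_weights.json, results/weight_search_trace.csv,",
    "results/score_threshold_metrics.json\n")
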