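#!/usr/bin/env Rscript
# Step 5: discrimination and operating characteristics.
#
# ROC/AUC for the full, slim and composite models, DeLong tests for the
# improvement from adding the imaging score, the score-only ROC, and
# PPV/NPV of the composite model at the default 0.5 probability cutoff and
# at the Youden-optimal cutoff.

suppressPackageStartupMessages(library(ndiscore))

coh <- load_cohort("results/cohort.csv")
models <- list(full = fit_logistic(coh, model_spec("full")),
               slim = fit_logistic(coh, model_spec("slim")),
               composite = fit_logistic(coh, model_spec("composite")))
labels <- labeled_cohort(coh)$severe

aucs <- list()
for (nm in names(models)) {
  ev <- evaluate_model(models[[nm]], coh)
  aucs[[nm]] <- ev$roc
  write.csv(ev$roc$points, sprintf("results/roc_%s.csv", nm),
            row.names = FALSE)
  cat(sprintf("%-9s AUC = %.3f (DeLong SE %.3f)\n", nm, ev$roc$auc,
              sqrt(ev$roc$delong_var)))
}
score_roc <- auc(cohort_scores(coh), labels)
cat(sprintf("%-9s AUC = %.3f (imaging score alone)\n", "score", score_roc$auc))

p_slim <- predict_cohort(models$slim, coh)
p_comp <- predict_cohort(models$composite, coh)
p_full <- predict_cohort(models$full, coh)
d1 <- delong_test(p_comp, p_slim, labels)
d2 <- delong_test(p_comp, p_full, labels)
cat(sprintf("\nDeLong composite vs slim: dAUC = %.3f, p = %.4g\n",
            d1$difference, d1$p_value))
cat(sprintf("DeLong composite vs full: dAUC = %.3f, p = %.4g\n",
            d2$difference, d2$p_value))

cat("\nComposite model operating characteristics:\n")
ev50 <- evaluate_model(models$composite, coh, threshold = 0.5)
evyj <- evaluate_model(models$composite, coh, threshold = "youden")
cat("  probability > 0.5:    "); print(ev50$metrics)
cat("  Youden-optimal cutoff:"); print(evyj$metrics)

jsonlite::write_json(
  list(seed = 2018L,
       auc = lapply(aucs, function(r) r$auc),
       auc_score_only = score_roc$auc,
       delong_composite_vs_slim = d1[c("difference", "p_value")],
       delong_composite_vs_full = d2[c("difference", "p_value")],
       composite_at_0.5 = ev50$metrics[c("sensitivity", "specificity",
                                         "ppv", "npv")],
       composite_at_youden = c(list(threshold = evyj$metrics$threshold),
                               evyj$metrics[c("sensitivity", "specificity",
                                              "ppv", "npv")])),
  "results/evaluation.json", auto_unbox = TRUE, digits = NA)
cat("Wrote results/roc_*.csv and results/evaluation.json\n")
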