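#!/usr/bin/env Rscript
# Step 4: clinical and composite logistic risk models.
#
# Fits the "full" clinical model (eight pre-specified covariates), the
# "slim" clinical model (the published parsimonious set), a stepwise
# reselection from all clinical candidates on this cohort, and the
# composite model (slim + MRI injury score). Coefficients, AIC, both
# pseudo-R2 variants and VIFs are written per model; no covariate should
# exceed the VIF > 5 collinearity flag.

suppressPackageStartupMessages(library(ndiscore))

coh <- load_cohort("results/cohort.csv")

models <- list(full = fit_logistic(coh, model_spec("full")),
               slim = fit_logistic(coh, model_spec("slim")),
               composite = fit_logistic(coh, model_spec("composite")))
stepwise <- tryCatch(backward_stepwise_aic(coh), error = function(e) {
  cat("stepwise reselection refused:", conditionMessage(e), "\n")
  NULL
})

for (nm in names(models)) {
  cat("\n==", nm, "model ==\n")
  print(models[[nm]])
  write_model_json(models[[nm]], sprintf("results/model_%s.json", nm))
}
if (!is.null(stepwise)) {
  cat("\n== stepwise-reselected clinical model ==\n")
  cat("dropped, in order:", paste(stepwise$dropped, collapse = ", "), "\n")
  print(stepwise)
  write_model_json(stepwise, "results/model_stepwise.json")
}

summary_df <- do.call(rbind, lapply(names(models), function(nm) {
  m <- models[[nm]]
  data.frame(model = nm, n = m$n_used, k = length(m$coefficients),
             aic = round(m$aic, 1),
             r2_mcfadden = round(m$pseudo_r2[["mcfadden"]], 3),
             r2_nagelkerke = round(m$pseudo_r2[["nagelkerke"]], 3),
             max_vif = round(max(m$vif), 2))
}))
write.csv(summary_df, "results/model_summary.csv", row.names = FALSE)
cat("\n")
print(summary_df, row.names = FALSE)

# calculator-style example: the same clinical picture with and without
# severe MRI findings
comp <- models$composite
hi <- predict_risk(comp, list(ventilator_days = 30, vaginal_delivery = 0,
                              antenatal_steroids_any = 1, severe_rop = 0,
                              ivh_grade = "IV", wmi_lesion_count = 1,
                              wmi_cystic = TRUE))
lo <- predict_risk(comp, list(ventilator_days = 30, vaginal_delivery = 0,
                              antenatal_steroids_any = 1, severe_rop = 0,
                              imaging_score = 0))
cat(sprintf("\nExample prediction, 30 ventilator days, steroids given:\n"))
cat(sprintf("  grade IV IVH + cystic WMI (score 10): %.2f +/- %.2f\n",
            hi$probability, hi$se))
cat(sprintf("  no MRI injury (score 0):              %.2f +/- %.2f\n",
            lo$probability, lo$se))
cat("Wrote results/model_*.json and results/model_summary.csv\n")
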