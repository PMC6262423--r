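# ndiscore

Risk prediction for **severe neurodevelopmental impairment in very preterm
infants** (born ≤ 30 weeks gestation) from term-equivalent-age MRI findings
and routine clinical factors.

An infant is labeled *severe* when any one Bayley-III composite score
(cognitive, motor, language; normative mean 100, SD 15) at 18–24 months
corrected age is ≤ 70. The package implements, on top of that labeling
rule:

* **A weighted three-domain MRI injury score.** Intraventricular
  hemorrhage (IVH, Papile grade), white matter injury (WMI), and
  cerebellar hemorrhage (CH) each contribute integer points:

  | Domain | Level | Points |
  |---|---|---|
  | CH size | large (>50% hemisphere) / punctate–small / none | 3 / 1 / 0 |
  | CH laterality | bilateral / unilateral | +1 / 0 |
  | IVH | grade III–IV / grade I–II / none | 5 / 2 / 0 |
  | WMI | multiple punctate (>2) or cystic / isolated punctate (≤2) / none | 5 / 2 / 0 |

  Total score S ∈ [0, 14]; predicted-severe iff S > 8 (strict).
* **A greedy integer weight learner** that escalates one feature at a time
  from an equal-weight baseline, accepting an increment while sensitivity
  strictly increases and specificity does not decrease at a recomputed
  Youden-optimal integer threshold, with exact-rational comparisons.
* **Clinical and composite logistic models** — a pre-specified 8-covariate
  "full" clinical model, the parsimonious "slim" model (ventilator days,
  vaginal delivery, antenatal steroids, severe ROP), backwards stepwise
  AIC reselection, and the composite model (slim + imaging score) — with
  AIC, McFadden/Nagelkerke pseudo-R², VIF collinearity screening, and
  per-subject predicted probability ± delta-method SE (the "calculator").
* **Evaluation**: ROC/AUC with DeLong variance, the paired DeLong test for
  correlated ROCs, PPV/NPV/Youden operating metrics, and the
  group-comparison cohort tables (Fisher's exact, Mann–Whitney U).
* **A seeded synthetic cohort generator** matching the published
  group-conditional cohort structure (154 infants, 25% severe prevalence),
  so the entire pipeline runs with no data download.

## Worked example

```r
library(ndiscore)

coh <- simulate_cohort(seed = 2018)      # 154 infants, published structure
table(coh$severe)
#> FALSE  TRUE
#>   118    36

s <- cohort_scores(coh, final_weights())
round(c(severe = mean(s[coh$severe]), other = mean(s[!coh$severe])), 1)
#> severe  other
#>    7.5    2.8

operating_metrics(s, coh$severe, 8)      # the published >8 operating point
#> threshold > 8: sens 44%, spec 97%, PPV 84%, NPV 85% (TP 16 FP 3 TN 115 FN 20)

slim <- fit_logistic(coh, model_spec("slim"))
comp <- fit_logistic(coh, model_spec("composite"))
comp
#> <ndi_model 'composite'> n = 154, AIC = 73.3, R2(Nagelkerke) = 0.751, R2(McFadden) = 0.634
#>            (Intercept)        ventilator_days       vaginal_delivery
#>                -3.2632                 0.1039                 0.6295
#> antenatal_steroids_any             severe_rop          imaging_score
#>                -2.4933                 1.0508                 0.3398
#> VIF: ventilator_days=1.25, vaginal_delivery=1.04, antenatal_steroids_any=1.07, severe_rop=1.03, imaging_score=1.18

# the calculator: same clinical picture, with and without severe MRI injury
predict_risk(comp, list(ventilator_days = 30, vaginal_delivery = 0,
                        antenatal_steroids_any = 1, severe_rop = 0,
                        ivh_grade = "IV", wmi_lesion_count = 1,
                        wmi_cystic = TRUE))$probability
#> [1] 0.6809667
predict_risk(comp, list(ventilator_days = 30, vaginal_delivery = 0,
                        antenatal_steroids_any = 1, severe_rop = 0,
                        imaging_score = 0))$probability
#> [1] 0.06665185
```

The imaging score moves this infant's predicted risk from 7% to 68%.
Because the generator samples covariates conditionally independent given
the outcome (only per-group marginals are published), absolute
discrimination on synthetic cohorts runs higher than the published
clinical AUCs; see the methods vignette
(`vignettes/mri-injury-score-methods.Rmd`) for what the synthetic testbed
does and does not establish.

## The analysis workflow

Numbered drivers under `analysis/` run the full study pipeline from the
repository root and write their tables under `results/`:

```sh
Rscript analysis/01_simulate_cohort.R   # cohort.csv
Rscript analysis/02_cohort_tables.R     # clinical/imaging comparison tables
Rscript analysis/03_score_weights.R     # score distribution, >8 metrics, weight search
Rscript analysis/04_risk_models.R       # full/slim/stepwise/composite fits
Rscript analysis/05_evaluate_models.R   # AUCs, DeLong tests, PPV/NPV
```

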