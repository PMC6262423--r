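---
title: "Methods: the weighted MRI injury score and composite risk models"
author: "ndiscore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the weighted MRI injury score and composite risk models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ndiscore)
```

## The prediction problem

Very preterm infants (born at or before 30 weeks gestation) face three
common forms of brain injury visible on a term-equivalent-age MRI:
intraventricular hemorrhage (IVH), white matter injury (WMI), and
cerebellar hemorrhage (CH). The outcome of interest is **severe
neurodevelopmental impairment** at 18--24 months corrected age, defined on
the Bayley-III assessment: an infant is labeled severe when *any one* of
the three composite scores (cognitive, motor, language; normative mean
100, SD 15) is at or below 70, i.e. more than two standard deviations
below the mean. `label_severe()` implements exactly this rule and is the
single source of truth: a `severe` column in an input file is ignored and
re-derived, so a cohort can never carry a label inconsistent with its
scores. Infants without all three composites cannot be labeled and are
excluded from modeling (`labeled_cohort()`).

## The weighted three-domain score

Each infant's MRI findings are summarized by an `injury_profile`: Papile
IVH grade, CH size and laterality, and WMI punctate-lesion count plus a
cystic flag. Findings collapse to scored levels:

* IVH: none / low-grade (I--II) / high-grade (III--IV);
* WMI: none / isolated punctate (1--2 lesions, no cysts) / multiple
  punctate (>2) or cystic, with cystic change dominating the count;
* CH: none / punctate-small (<50% of a cerebellar hemisphere) / large
  (>50%), with a separate bonus for bilateral hemorrhage.

The total score is the sum of the three domain scores. The final
weighting (`final_weights()`) is: large CH 3, punctate/small CH 1,
bilateral CH +1, high-grade IVH 5, low-grade IVH 2, multiple/cystic WMI
5, isolated punctate WMI 2 -- so the score runs from 0 (no injury) to 14
(large bilateral CH, high-grade IVH, multiple/cystic WMI). The published
operating point classifies an infant as predicted-severe when the score
is *strictly greater than* 8; every threshold comparison in the package
uses that strict convention.

Two representational choices deserve a note. The source tables
distinguish "punctate" from "small" CH but score them identically, so the
profile stores the merged `punctate_or_small` level and the CSV reader
accepts either synonym. And a cystic flag with a zero lesion count is
rejected at validation: a cyst is itself a lesion.

## The greedy weight search

`learn_weights()` implements the iterative weighting procedure that
produced the final table. Starting from an equal-weight baseline (0
points absent, 1 point present), the point value of one injury feature at
a time is raised by one; after each proposal the cohort is rescored, an
integer operating threshold is chosen, and the proposal is **accepted
while sensitivity strictly increases and specificity does not decrease**
relative to the last accepted state. The search then moves to the next
feature; a per-level cap (default 10) bounds the iteration count at
7 x 10 proposals.

Choices the procedure's description leaves open, fixed here:

* **Threshold inside the search.** Unstated in the source; we recompute
  the Youden-optimal integer threshold at every proposal (ties broken
  toward the lowest threshold), with a `fixed:k` alternative for
  sensitivity analysis. The Youden choice is parameter-free and
  reproducible.
* **Feature order.** Unstated; default is descending clinical severity
  (`ivh_high`, `wmi_multiple_or_cystic`, `ch_large`, `ivh_low`,
  `wmi_isolated`, `ch_small`, `ch_bilateral_bonus`). Results are
  order-dependent and the order is an explicit, recorded parameter.
* **Baseline granularity.** "One point per present feature" can mean the
  four domains or the seven scored levels; both yield the identical
  all-ones table (only one level per domain is active in any profile), so
  the per-profile baseline maximum is 4.
* **Arithmetic.** Sensitivity and specificity are carried as exact
  integer rationals, so acceptance can never hinge on floating-point
  rounding, and permuting subjects cannot change the result (a property
  the test suite asserts).
* **Domain ordering.** Intermediate states may place more points on a
  milder level; after the search the severe level of each domain is
  raised to at least the milder level's value, with a warning when this
  repair binds.

**A property worth knowing before using the learner.** The acceptance
rule demands a strict Pareto improvement of the confusion matrix from a
single one-point increment. On statistically realistic cohorts -- where
every injury feature occurs in both outcome groups -- such increments
essentially never exist: we scanned all one-step weight tables and all
integer thresholds on score-model cohorts with effect sizes up to
near-deterministic and found no admissible move from the baseline
operating point. The learner is therefore deliberately conservative: on
noisy data it retains the baseline, and it escalates exactly when the
cohort carries clean feature--outcome structure (the test suite
demonstrates both regimes, and checks the greedy path against an
independent reference implementation on small instances). For this reason
the package treats the published weight table as a fixed reference
(`final_weights()`) and the learner as a separately documented procedure,
rather than claiming the former is the reproducible output of the latter.

## Risk models

Three logistic regressions of the severe label are pre-specified
(`model_spec()`):

* **full**: gestational age, birth weight, any antenatal steroids, 5-min
  Apgar, postnatal steroids, ventilator days, inotrope use, severe ROP;
* **slim**: ventilator days, vaginal delivery, any antenatal steroids,
  severe ROP -- the published parsimonious set;
* **composite**: slim plus the MRI injury score.

Fits are maximum likelihood via iteratively reweighted least squares
(`stats::glm`, convergence tolerance 1e-10, at most 100 iterations), with
complete-case analysis per model; continuous covariates enter
untransformed and uncentered. Race describes the cohort only and is never
a model covariate. Alongside the coefficients and their covariance
(inverse observed information) each fit reports AIC, both McFadden and
Nagelkerke pseudo-R^2 (which one the source reports is unstated, so both
are shown; Nagelkerke is the default display as the more common
convention in the clinical literature), and per-covariate variance
inflation factors computed as 1/(1 - R^2) from the least-squares
regression of each covariate on the others, flagged above 5. Perfect or
quasi-separation (degenerate fitted probabilities with a divergent
coefficient) and rank-deficient designs are refused with the offending
covariate named -- a realistic hazard at n = 154 for rare binaries such
as seizures.

`backward_stepwise_aic()` reproduces the parsimonious-model construction:
from all collected clinical covariates, repeatedly delete the single
covariate whose removal lowers AIC most, stopping when no deletion
lowers it, with ties broken deterministically toward the covariate latest
in the candidate ordering. On cohorts from the synthetic generator the
stepwise-selected model beats the full model on AIC in almost every seed.
The *fixed published slim set*, however, does not reliably out-AIC the
full model here: under the generator's conditional-independence design
(below) the full model's extra covariates each carry independent signal.
This is a property of the testbed, not of the method, and is asserted
accordingly in the tests.

`predict_risk()` is the calculator: probability = inverse-logit of the
linear predictor, with a delta-method standard error
`p(1-p) * sqrt(x' Sigma x)` (validated against a parametric bootstrap
from the coefficient distribution in the tests). For the composite model
it accepts either an explicit `imaging_score` or raw injury findings,
which it scores on the fly.

## Evaluation

ROC curves, AUC and its DeLong variance, and the paired DeLong test for
correlated ROCs are delegated to pROC; the test suite independently
verifies the AUC against brute-force pair enumeration (ties counting one
half) and the DeLong variance against a stratified bootstrap.
`operating_metrics()` reports the confusion matrix and derived rates at
any cutoff under the strict `>` rule, with undefined PPV/NPV returned as
missing rather than zero. The composite model's operating point is
reported both at probability 0.5 (default) and at the Youden-optimal
cutoff, since the source does not state which was used.

Cohort description uses Fisher's exact test for binaries (two-sided by
the point-probability convention -- stated because two-sided definitions
differ), a Monte-Carlo Freeman--Halton extension for the r x c race
table (1e5 draws, seeded, reported with its Monte-Carlo standard error),
and the Mann-Whitney U test for continuous variables (exact enumeration
for small untied samples, otherwise the tie- and continuity-corrected
normal approximation). `cohort_report()` assembles the two
group-comparison tables with n (%), mean (SD) or median (range) per
group and stars at p < 0.05.

## The synthetic cohort generator

No patient-level data accompany the source, so `simulate_cohort()`
emulates the published cohort structure: 154 infants, severe prevalence
38/154, and *group-conditional* distributions matched to the printed
per-group statistics -- truncated normals for gestational age (22--30
weeks) and birth weight (>= 300 g) at the printed means/SDs; Bernoulli
rates from the printed percentages for all binaries; injury-category
multinomials from the printed per-group counts (IVH none/low/high, CH
none/small/large with bilaterality conditional on CH presence, WMI
none/isolated/multiple); a binomial(9, median/9) 5-min Apgar whose
medians reproduce the printed 6 vs 5.5; log-normal ventilator days
parameterized by the printed per-group medians (4 vs 31.5 days; the
spread, sdlog 1.3 and 1.0, was sized once to the printed ranges);
and group-conditional normal Bayley-III components rejected until
consistent with the label (severe: minimum component <= 70; otherwise all
> 70), after which the label is re-derived, so generated cohorts pass
validation by construction. Impossible configurations (e.g. a severe
group mean far above 70 with tiny SD) error after a bounded number of
rejection rounds rather than looping. Within the "multiple punctate or
cystic" WMI category, half of draws are cystic and lesion counts are
3 + Poisson(2) (or 1 + Poisson(2) when cystic) -- values chosen once as
clinically plausible, since only the category frequencies are published.

The key structural limitation is deliberate and documented: covariates
are drawn **conditionally independent given the outcome group**, because
only per-group marginals are published. Real clinical covariates are
strongly cross-correlated (ventilator days with BPD and inotropes, for
instance), so the generator overstates the *joint* information in the
covariate set: fitted clinical models discriminate better here (AUC near
0.95) than the modest published clinical AUCs, and the published headline
quantities (AUC 0.850, PPV 76%, NPV 90%, the 127.8 vs 132.1 AIC ordering
of the fixed slim and full sets, mean scores 8.1 vs 3.5) are treated as
directional properties, not reproducible targets. What passing tests do
show: the scoring arithmetic is exact, the estimators agree with
closed-form and brute-force oracles, group-conditional margins of the
generator match the configuration at Monte-Carlo precision, and adding a
truly informative imaging score to a clinical model yields a
DeLong-significant AUC improvement in >= 18 of 20 seeded cohorts.

`simulate_from_score_model()` is the parameter-recovery testbed: profiles
from the outcome-marginal mixture, severe drawn from
`plogis(intercept + beta * score)` (defaults beta = 0.5 per point,
intercept = -2.8, giving roughly the development cohort's 25%
prevalence), clinical covariates and Bayley scores then filled in
group-conditionally. Logistic fits on such cohorts recover the
generating coefficients within Monte-Carlo error (asserted at n = 500
and 5000).

## Problem sizes and runtime choices

The test suite checks generator margins at n = 20000 (binomial 3-SE
tolerances), parameter recovery at n = 500--5000, the DeLong improvement
property over 20 seeds at n = 2000, learner/oracle equivalence on
cohorts of 6--12 subjects with weight cap 3, and the Fisher exhaustive
oracle on 200 random small tables; these sizes keep every suite a few
seconds to a couple of minutes on one CPU while leaving Monte-Carlo
tolerances comfortably non-trivial.

## Known limitations

* The learner is faithful to the described acceptance rule and therefore
  conservative under noise (see above); it is not a global optimizer, and
  no claim is made that the published weights are its reproducible
  output.
* The generator models no cross-covariate correlation within outcome
  groups and no site effects; absolute discrimination measured on it does
  not transfer to real cohorts.
* Infants too impaired to complete the Bayley-III cannot be labeled by
  the rule and are excluded, mirroring the source cohort's handling;
  this likely biases severity downward in any real application.
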