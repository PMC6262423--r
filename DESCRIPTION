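Package: ndiscore
Title: Weighted MRI Injury Scoring and Clinical Risk Models for Severe
    Neurodevelopmental Impairment in Preterm Infants
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements a three-domain (intraventricular hemorrhage, white
    matter injury, cerebellar hemorrhage) weighted MRI injury score for
    preterm infants scanned at term-equivalent age, a greedy integer
    weight-learning procedure driven by sensitivity and specificity,
    clinical and composite logistic risk models for severe
    neurodevelopmental impairment (any Bayley-III composite at or below 70
    at 18-24 months), model evaluation (ROC/AUC, DeLong comparison of
    correlated ROCs, variance inflation factors, operating
    characteristics), cohort description tables (Fisher's exact test,
    Mann-Whitney U), and a seeded synthetic preterm-cohort generator so
    the entire pipeline runs without access to patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pROC,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
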