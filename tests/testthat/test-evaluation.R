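test_that("AUC equals the brute-force pair statistic, ties counted half", {
  # perfectly separated
  expect_equal(auc(c(5, 6, 1, 2), c(TRUE, TRUE, FALSE, FALSE))$auc, 1.0)
  # 6-subject vector with ties, against exhaustive pair enumeration
  s <- c(3, 1, 4, 4, 2, 1); l <- c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE)
  expect_equal(auc(s, l)$auc, bruteforce_auc(s, l))
  # random instances
  set.seed(13)
  for (i in 1:25) {
    n <- sample(8:40, 1)
    s <- sample(0:14, n, TRUE)
    l <- sample(c(TRUE, FALSE), n, TRUE)
    if (all(l) || !any(l)) next
    expect_equal(auc(s, l)$auc, bruteforce_auc(s, l))
  }
  expect_error(auc(1:3, c(TRUE, TRUE, TRUE)), "both outcome classes")
})

test_that("AUC symmetry and monotone-transform invariance", {
  set.seed(14)
  s <- rnorm(60); l <- rbinom(60, 1, 0.4) == 1
  r <- auc(s, l)
  expect_equal(r$auc + auc(-s, l)$auc, 1)
  for (f in list(function(x) 3 * x + 2, exp, function(x) x^3))
    expect_equal(auc(f(s), l)$auc, r$auc)
  # the ROC polygon is a staircase from (0,0) to (1,1)
  expect_equal(r$points[1, ], data.frame(fpr = 0, tpr = 0),
               ignore_attr = TRUE)
  expect_equal(unlist(r$points[nrow(r$points), ]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(r$points$fpr) >= 0))
  expect_true(all(diff(r$points$tpr) >= 0))
  # trapezoidal area under the curve equals the pair statistic
  area <- sum(diff(r$points$fpr) *
                (head(r$points$tpr, -1) + tail(r$points$tpr, -1)) / 2)
  expect_equal(area, r$auc, tolerance = 1e-12)
})

test_that("DeLong self-comparison gives difference 0 and p = 1", {
  set.seed(15)
  s <- rnorm(50); l <- rbinom(50, 1, 0.5) == 1
  d <- delong_test(s, s, l)
  expect_equal(d$difference, 0)
  expect_equal(d$p_value, 1)
})

test_that("DeLong comparison is antisymmetric in its two models", {
  set.seed(16)
  l <- rbinom(80, 1, 0.4) == 1
  a <- rnorm(80) + l; b <- rnorm(80) + 0.5 * l
  d1 <- delong_test(a, b, l)
  d2 <- delong_test(b, a, l)
  expect_equal(d1$difference, -d2$difference)
  expect_equal(d1$p_value, d2$p_value)
  expect_error(delong_test(a, b[-1], l), "same subjects")
})

test_that("DeLong variance agrees with a bootstrap on a fixed instance", {
  set.seed(17)
  n <- 120
  l <- rep(c(TRUE, FALSE), c(45, 75))
  a <- rnorm(n) + 1.2 * l
  b <- 0.6 * a + rnorm(n, sd = 0.8) + 0.4 * l
  d <- delong_test(a, b, l)
  boot <- replicate(2000, {
    idx <- c(sample(which(l), replace = TRUE),
             sample(which(!l), replace = TRUE))
    bruteforce_auc(a[idx], l[idx]) - bruteforce_auc(b[idx], l[idx])
  })
  expect_equal(d$variance, var(boot), tolerance = 0.15)
})

test_that("operating metrics recover a constructed confusion matrix", {
  # TP=3 FP=1 TN=8 FN=2 at threshold 5
  values <- c(9, 8, 7, 6, 3, 2, rep(1, 7), 4)
  labels <- c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, rep(FALSE, 8))
  m <- operating_metrics(values, labels, 5)
  expect_equal(c(m$tp, m$fp, m$tn, m$fn), c(3, 1, 8, 2))
  expect_equal(m$ppv, 0.75)
  expect_equal(m$npv, 0.8)
  expect_equal(m$youden_j, m$sensitivity + m$specificity - 1)
  expect_equal(m$tp + m$fp + m$tn + m$fn, length(values))
  # perfect classifier
  p <- operating_metrics(c(1, 1, 0, 0), c(TRUE, TRUE, FALSE, FALSE), 0.5)
  expect_equal(c(p$sensitivity, p$specificity, p$ppv, p$npv), rep(1, 4))
  # threshold above everything: nothing predicted positive, PPV undefined
  q <- operating_metrics(c(1, 2, 3), c(TRUE, FALSE, TRUE), 10)
  expect_equal(q$sensitivity, 0)
  expect_equal(q$specificity, 1)
  expect_true(is.na(q$ppv))
})

test_that("2x2 Fisher matches exhaustive hypergeometric enumeration", {
  expect_equal(fisher_exact_2x2(matrix(c(6, 3, 4, 2), 2)), 1)  # proportional
  set.seed(18)
  for (i in 1:200) {
    tab <- matrix(rpois(4, sample(1:7, 1)), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact_2x2(tab), enumerate_fisher_2x2(tab),
                 tolerance = 1e-10)
  }
  expect_error(fisher_exact_2x2(matrix(c(-1, 2, 3, 4), 2)), "non-negative")
  expect_error(fisher_exact_2x2(matrix(c(0.5, 2, 3, 4), 2)), "integers")
})

test_that("Monte-Carlo r x c Fisher agrees with the exact 2x2 test", {
  tab <- matrix(c(12, 5, 7, 14), 2)
  exact <- fisher_exact_2x2(tab)
  mc <- fisher_exact_rxc(tab, B = 2e4, seed = 7)
  expect_lt(abs(mc$p_value - exact), 3 * mc$mc_se + 1e-3)
  # proportional rows: p near 1
  prop <- fisher_exact_rxc(matrix(c(10, 20, 5, 10, 15, 30), 2), B = 1e4,
                           seed = 7)
  expect_gt(prop$p_value, 0.95)
  # degenerate single effective column
  expect_equal(fisher_exact_rxc(matrix(c(5, 3, 0, 0), 2))$p_value, 1)
  # same seed, same estimate; caller's RNG stream is untouched
  expect_equal(fisher_exact_rxc(tab, B = 5e3, seed = 3)$p_value,
               fisher_exact_rxc(tab, B = 5e3, seed = 3)$p_value)
})

test_that("Mann-Whitney U: exact small-sample p and the rank-sum identity", {
  # complete separation, 4 vs 4, no ties: exact two-sided p = 2/70
  r <- mann_whitney_u(c(1, 2, 3, 4), c(5, 6, 7, 8))
  expect_true(r$exact)
  expect_equal(r$p_value, 2 / 70)
  # identical samples: p near 1 under the normal approximation
  x <- c(1.2, 3.4, 2.2, 5.1, 4.4, 3.3, 2.8, 1.9, 4.0, 3.1,
         2.5, 3.9, 1.4, 4.8, 3.6, 2.0)
  r2 <- mann_whitney_u(x, x)
  expect_gt(r2$p_value, 0.9)
  # U_x + U_y = n_x * n_y
  set.seed(19)
  for (i in 1:20) {
    a <- rnorm(sample(3:15, 1)); b <- rnorm(sample(3:15, 1))
    expect_equal(mann_whitney_u(a, b)$U + mann_whitney_u(b, a)$U,
                 length(a) * length(b))
  }
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("the cohort report regenerates the comparison-table structure", {
  coh <- simulate_cohort(seed = 23)
  rep <- cohort_report(coh)
  expect_named(rep, c("clinical", "imaging"))
  for (nm in c("Gestational age", "Birth weight", "Any antenatal steroids",
               "Ventilator days", "Severe ROP", "Bayley-III cognitive"))
    expect_true(any(grepl(nm, rep$clinical$variable)), info = nm)
  for (nm in c("Any IVH", "Grade III/IV IVH", "Any cerebellar hemorrhage",
               "Bilateral cerebellar", "Any brain injury"))
    expect_true(any(grepl(nm, rep$imaging$variable)), info = nm)

  # group percentages in a binary row equal round(100 * count / group n)
  df <- as.data.frame(labeled_cohort(coh))
  row <- rep$clinical[grepl("Severe ROP", rep$clinical$variable), ]
  k <- sum(df$severe_rop & df$severe)
  expect_equal(row$severe, sprintf("%d (%d)", k, pct(k, sum(df$severe))))

  # stars appear exactly on rows with p < 0.05 (a displayed "0.05" is
  # ambiguous under two-digit rounding, so those rows are not asserted)
  tab <- rbind(rep$clinical, rep$imaging)
  starred <- grepl("\\*", tab$p_value)
  pnum <- suppressWarnings(as.numeric(sub(" \\*", "", tab$p_value)))
  small <- grepl("^<0.01", tab$p_value)
  expect_true(all(starred[small]))
  has_p <- !is.na(pnum) & abs(pnum - 0.05) > 1e-9
  expect_equal(starred[has_p], pnum[has_p] < 0.05)
  expect_error(cohort_report(as_cohort(cohort_row("Z1"))),
               "both outcome classes")
})

test_that("model evaluation reports AUC and operating metrics coherently", {
  coh <- simulate_cohort(seed = 24)
  m <- fit_logistic(coh, model_spec("composite"))
  ev <- evaluate_model(m, coh, threshold = 0.5)
  expect_gt(ev$roc$auc, 0.5)
  expect_equal(ev$metrics$tp + ev$metrics$fp + ev$metrics$tn +
                 ev$metrics$fn, m$n_used)
  evy <- evaluate_model(m, coh, threshold = "youden")
  expect_gte(evy$metrics$youden_j, ev$metrics$youden_j - 1e-12)
})
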