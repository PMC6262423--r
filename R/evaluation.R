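## ROC/AUC and DeLong comparisons are delegated to pROC; descriptive
## cohort comparisons use the exact tests in stats. The operating-metric
## bookkeeping (confusion counts, PPV/NPV, Youden) is local.

roc_obj <- function(scores, labels) {
  labels <- as.logical(labels)
  if (!any(labels) || all(labels))
    stop("both outcome classes are required for ROC analysis")
  pROC::roc(response = labels, predictor = as.numeric(scores),
            levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
}

#' ROC curve and AUC with DeLong variance
#'
#' The AUC equals the Mann-Whitney pair statistic (ties count one half) and
#' the trapezoidal area under the empirical ROC over all distinct observed
#' cutpoints. Its variance is the DeLong structural-component estimator.
#'
#' @param scores numeric score or probability per subject (higher = more
#'   likely severe).
#' @param labels logical outcome per subject.
#' @return A `roc_result` list: `points` (data frame of FPR/TPR, from
#'   (0,0) to (1,1)), `auc`, `delong_var`, `n_pos`, `n_neg`.
#' @export
auc <- function(scores, labels) {
  r <- roc_obj(scores, labels)
  pts <- data.frame(fpr = rev(1 - r$specificities),
                    tpr = rev(r$sensitivities))
  structure(list(points = pts,
                 auc = as.numeric(pROC::auc(r)),
                 # a degenerate (AUC = 1) curve has zero DeLong variance;
                 # pROC flags it with a warning we do not propagate
                 delong_var = suppressWarnings(
                   as.numeric(pROC::var(r, method = "delong"))),
                 n_pos = sum(as.logical(labels)),
                 n_neg = sum(!as.logical(labels))),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC = %.3f (DeLong var %.2e), %d severe / %d not severe, %d ROC points\n",
              x$auc, x$delong_var, x$n_pos, x$n_neg, nrow(x$points)))
  invisible(x)
}

#' DeLong's test for two correlated ROC curves
#'
#' Compares the AUCs of two scores measured on the same subjects using the
#' paired DeLong (1988) structural-component estimator; the p-value comes
#' from the normal approximation.
#'
#' @param scores_a,scores_b the two score vectors (same subjects, same
#'   order).
#' @param labels logical outcome per subject.
#' @return List: `auc_a`, `auc_b`, `difference` (a - b), `variance` of the
#'   difference, `z`, `p_value` (two-sided).
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  if (length(scores_a) != length(scores_b))
    stop("score vectors must cover the same subjects")
  ra <- roc_obj(scores_a, labels)
  rb <- roc_obj(scores_b, labels)
  auc_a <- as.numeric(pROC::auc(ra))
  auc_b <- as.numeric(pROC::auc(rb))
  if (isTRUE(all.equal(as.numeric(scores_a), as.numeric(scores_b)))) {
    # identical scores: difference is exactly 0 with zero variance
    return(list(auc_a = auc_a, auc_b = auc_b, difference = 0,
                variance = 0, z = 0, p_value = 1))
  }
  tst <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  d <- auc_a - auc_b
  z <- as.numeric(tst$statistic)
  list(auc_a = auc_a, auc_b = auc_b, difference = d,
       variance = if (z != 0) (d / z)^2 else NA_real_,
       z = z, p_value = as.numeric(tst$p.value))
}

#' Operating characteristics at a threshold
#'
#' Confusion counts with predicted-positive iff `value > threshold`
#' (strict, consistent with the score threshold rule), and the derived
#' rates. PPV/NPV with a zero denominator are reported as `NA`, not 0.
#'
#' @param values numeric scores or probabilities.
#' @param labels logical outcomes.
#' @param threshold operating threshold.
#' @return An `eval_metrics` list: threshold, tp/fp/tn/fn, sensitivity,
#'   specificity, youden_j, ppv, npv.
#' @export
operating_metrics <- function(values, labels, threshold) {
  labels <- as.logical(labels)
  if (!any(labels) || all(labels))
    stop("both outcome classes are required")
  pred <- values > threshold
  tp <- sum(pred & labels); fp <- sum(pred & !labels)
  tn <- sum(!pred & !labels); fn <- sum(!pred & labels)
  sens <- tp / (tp + fn); spec <- tn / (tn + fp)
  structure(list(threshold = threshold, tp = tp, fp = fp, tn = tn, fn = fn,
                 sensitivity = sens, specificity = spec,
                 youden_j = sens + spec - 1,
                 ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
                 npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_),
            class = "eval_metrics")
}

#' @export
print.eval_metrics <- function(x, ...) {
  cat(sprintf("threshold > %s: sens %.0f%%, spec %.0f%%, PPV %s, NPV %s (TP %d FP %d TN %d FN %d)\n",
              format(x$threshold), 100 * x$sensitivity, 100 * x$specificity,
              if (is.na(x$ppv)) "-" else sprintf("%.0f%%", 100 * x$ppv),
              if (is.na(x$npv)) "-" else sprintf("%.0f%%", 100 * x$npv),
              x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact hypergeometric two-sided p by the point-probability method: the
#' sum of the probabilities of all tables (with the observed margins) whose
#' point probability does not exceed the observed table's. This is the
#' convention of [stats::fisher.test()], stated here because two-sided
#' definitions differ between packages.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return Two-sided p-value.
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  check_count_table(table)
  stopifnot(all(dim(table) == c(2L, 2L)))
  stats::fisher.test(table)$p.value
}

#' Fisher's exact test for an r x c table (Monte Carlo)
#'
#' Freeman-Halton extension estimated by Monte Carlo: tables are drawn with
#' the observed margins fixed and the point-probability criterion applied,
#' as in [stats::fisher.test()] with `simulate.p.value = TRUE`. The
#' Monte-Carlo standard error accompanies the estimate.
#'
#' @param table r x c matrix of non-negative integer counts.
#' @param B number of Monte-Carlo draws.
#' @param seed integer seed for the draws (local to this call).
#' @return List: `p_value`, `mc_se`, `B`. Degenerate tables with a single
#'   effective row or column return p = 1 exactly.
#' @export
fisher_exact_rxc <- function(table, B = 1e5, seed = 1L) {
  table <- as.matrix(table)
  check_count_table(table)
  keep_r <- rowSums(table) > 0; keep_c <- colSums(table) > 0
  tab <- table[keep_r, keep_c, drop = FALSE]
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    return(list(p_value = 1, mc_se = 0, B = 0L))
  p <- withr_seed(seed, function()
    stats::fisher.test(tab, simulate.p.value = TRUE, B = B)$p.value)
  list(p_value = p, mc_se = sqrt(p * (1 - p) / B), B = as.integer(B))
}

check_count_table <- function(table) {
  if (any(is.na(table)) || any(table < 0) || any(table != round(table)))
    stop("counts must be non-negative integers")
  invisible(table)
}

## run f() under a local RNG state so callers' streams are untouched
withr_seed <- function(seed, f) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  f()
}

#' Mann-Whitney U test
#'
#' U from rank sums with midranks for ties. The p-value is exact (by
#' enumeration) for small untied samples, otherwise the normal
#' approximation with tie correction and continuity correction is used, as
#' in [stats::wilcox.test()].
#'
#' @param x,y the two samples.
#' @return List: `U` (for sample `x`), `p_value` (two-sided), `exact`
#'   (logical: was the exact distribution used).
#' @export
mann_whitney_u <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L)
    stop("both samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0L
  use_exact <- !ties && (length(x) + length(y)) <= 12L
  wt <- stats::wilcox.test(x, y, exact = use_exact, correct = TRUE)
  list(U = unname(wt$statistic), p_value = wt$p.value, exact = use_exact)
}

#' Rounded percentage, as printed in clinical tables
#' @param count,n numerator and group size.
#' @return `round(100 * count / n)`.
#' @export
pct <- function(count, n) round(100 * count / n)

## row builders for the group-comparison report -------------------------

fmt_p <- function(p) {
  star <- if (!is.na(p) && p < 0.05) " *" else ""
  if (is.na(p)) return("")
  if (p < 0.01) paste0("<0.01", star)
  else paste0(formatC(p, digits = 2, format = "f"), star)
}

row_binary <- function(label, x, severe) {
  tab <- table(factor(!severe, levels = c(FALSE, TRUE)),
               factor(x, levels = c(TRUE, FALSE)))
  p <- fisher_exact_2x2(matrix(as.integer(tab), 2))
  data.frame(
    variable = paste0(label, ", n (%)"),
    no_severe = sprintf("%d (%d)", sum(x & !severe),
                        pct(sum(x & !severe), sum(!severe))),
    severe = sprintf("%d (%d)", sum(x & severe),
                     pct(sum(x & severe), sum(severe))),
    p_value = fmt_p(p), stringsAsFactors = FALSE)
}

row_mean_sd <- function(label, x, severe) {
  p <- mann_whitney_u(x[severe], x[!severe])$p_value
  data.frame(
    variable = paste0(label, ", mean (SD)"),
    no_severe = sprintf("%.1f (%.1f)", mean(x[!severe]), stats::sd(x[!severe])),
    severe = sprintf("%.1f (%.1f)", mean(x[severe]), stats::sd(x[severe])),
    p_value = fmt_p(p), stringsAsFactors = FALSE)
}

row_median_range <- function(label, x, severe) {
  p <- mann_whitney_u(x[severe], x[!severe])$p_value
  fmt <- function(v) sprintf("%s (%s-%s)",
                             format(stats::median(v)), format(min(v)),
                             format(max(v)))
  data.frame(
    variable = paste0(label, ", median (range)"),
    no_severe = fmt(x[!severe]), severe = fmt(x[severe]),
    p_value = fmt_p(p), stringsAsFactors = FALSE)
}

row_category <- function(label, x, severe, levels, seed = 1L) {
  tab <- table(factor(x, levels = levels), severe)
  p <- fisher_exact_rxc(unclass(tab), seed = seed)$p_value
  rows <- lapply(seq_along(levels), function(i) {
    data.frame(
      variable = paste0("  ", levels[i], ", n (%)"),
      no_severe = sprintf("%d (%d)", tab[i, 1], pct(tab[i, 1], sum(!severe))),
      severe = sprintf("%d (%d)", tab[i, 2], pct(tab[i, 2], sum(severe))),
      p_value = "", stringsAsFactors = FALSE)
  })
  head_row <- data.frame(variable = label, no_severe = "", severe = "",
                         p_value = fmt_p(p), stringsAsFactors = FALSE)
  do.call(rbind, c(list(head_row), rows))
}

#' Group-comparison report (clinical and imaging characteristics)
#'
#' Regenerates the structure of the published cohort-description tables:
#' infants with vs without severe impairment compared by Fisher's exact
#' test (categorical) and the Mann-Whitney U test (continuous), n (%),
#' mean (SD) or median (range) per group, and p-values starred at
#' p < 0.05.
#'
#' @param cohort a labeled `ndi_cohort`.
#' @param seed seed for the Monte-Carlo r x c test (race row).
#' @return List of two data frames, `clinical` and `imaging`.
#' @export
cohort_report <- function(cohort, seed = 1L) {
  df <- as.data.frame(labeled_cohort(cohort))
  s <- df$severe
  clinical <- rbind(
    row_mean_sd("Gestational age (weeks)", df$gestational_age, s),
    row_mean_sd("Birth weight (grams)", df$birth_weight, s),
    row_binary("SGA", df$sga, s),
    row_binary("Male sex", df$male, s),
    row_category("Race", df$race, s, .race_levels, seed = seed),
    row_binary("Pre-eclampsia", df$preeclampsia, s),
    row_binary("Chorioamnionitis", df$chorioamnionitis, s),
    row_binary("Vaginal delivery", df$vaginal_delivery, s),
    row_binary("Any antenatal steroids", df$antenatal_steroids_any, s),
    row_binary("Complete antenatal steroids", df$antenatal_steroids_complete, s),
    row_binary("Antenatal magnesium sulfate", df$antenatal_magnesium, s),
    row_median_range("5-min Apgar score", df$apgar5, s),
    row_binary("Postnatal steroids", df$postnatal_steroids, s),
    row_median_range("Ventilator days", df$ventilator_days, s),
    row_binary("BPD diagnosis", df$bpd, s),
    row_binary("Inotropic medication administration", df$inotropes, s),
    row_binary("Culture-positive sepsis", df$sepsis, s),
    row_binary("Necrotizing enterocolitis", df$nec, s),
    row_binary("PDA ligation", df$pda_ligation, s),
    row_binary("Clinically apparent seizures", df$seizures, s),
    row_binary("Severe ROP", df$severe_rop, s),
    row_mean_sd("Bayley-III cognitive score", df$bayley_cognitive, s),
    row_mean_sd("Bayley-III motor score", df$bayley_motor, s),
    row_mean_sd("Bayley-III language score", df$bayley_language, s))
  ivh_cat <- classify_ivh(df$ivh_grade)
  wmi_cat <- classify_wmi(df$wmi_lesions, df$wmi_cystic)
  any_injury <- ivh_cat != "none" | df$ch_size != "none" | wmi_cat != "none"
  imaging <- rbind(
    row_binary("Any IVH", ivh_cat != "none", s),
    row_binary("Grade III/IV IVH", ivh_cat == "high", s),
    row_binary("Any cerebellar hemorrhage", df$ch_size != "none", s),
    row_binary("Large cerebellar hemorrhage", df$ch_size == "large", s),
    row_binary("Punctate/small cerebellar hemorrhage",
               df$ch_size == "punctate_or_small", s),
    row_binary("Bilateral cerebellar hemorrhage", df$ch_bilateral, s),
    row_binary("WMI multiple punctate or cystic",
               wmi_cat == "multiple_or_cystic", s),
    row_binary("WMI isolated punctate", wmi_cat == "isolated_punctate", s),
    row_binary("Any brain injury", any_injury, s))
  rownames(clinical) <- rownames(imaging) <- NULL
  list(clinical = clinical, imaging = imaging)
}

#' Evaluate a fitted risk model on a cohort
#'
#' ROC/AUC with DeLong variance plus operating metrics at a probability
#' cutoff. The default operating point is 0.5; `threshold = "youden"`
#' picks the probability cutoff maximizing Youden's J.
#'
#' @param model a fitted `ndi_model`.
#' @param cohort a labeled `ndi_cohort`.
#' @param threshold numeric probability cutoff, or `"youden"`.
#' @param weights [weight_table()] for `imaging_score`, if needed.
#' @return List: `roc` (a `roc_result`) and `metrics` (an `eval_metrics`).
#' @export
evaluate_model <- function(model, cohort, threshold = 0.5,
                           weights = final_weights()) {
  mf <- model_frame(cohort, model$spec$covariates, weights)
  p <- as.numeric(stats::predict(model$glm, newdata = mf,
                                 type = "response"))
  labels <- mf$severe
  r <- auc(p, labels)
  if (identical(threshold, "youden")) {
    # candidate cutpoints under the strict ">" rule: every observed value
    # (plus one below the minimum, i.e. predict-all-positive)
    cand <- c(min(p) - 1, sort(unique(p)))
    j <- vapply(cand, function(t)
      operating_metrics(p, labels, t)$youden_j, numeric(1))
    threshold <- cand[which.max(j)]
  }
  list(roc = r, metrics = operating_metrics(p, labels, threshold))
}
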