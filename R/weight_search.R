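## Greedy integer weight learning for the MRI injury score.
##
## Sensitivity and specificity are carried as exact rationals (integer
## numerator/denominator) so that the acceptance comparisons "sensitivity
## strictly increased" / "specificity did not decrease" are free of
## floating-point ties. With cohort sizes in the hundreds the cross
## products stay far below 2^53, so plain doubles hold them exactly.

rational <- function(num, den) c(num = as.numeric(num), den = as.numeric(den))
rat_gt <- function(a, b) a["num"] * b["den"] > b["num"] * a["den"]
rat_ge <- function(a, b) a["num"] * b["den"] >= b["num"] * a["den"]
rat_value <- function(a) unname(a["num"] / a["den"])

#' Sensitivity and specificity at an integer score threshold
#'
#' Predicted positive iff `score > threshold` (strict). Returned as exact
#' rationals so that comparisons between candidate weightings never hinge
#' on floating-point rounding.
#'
#' @param scores integer score per subject.
#' @param labels logical outcome per subject (`TRUE` = severe).
#' @param threshold integer threshold.
#' @return List with `sensitivity` and `specificity`, each a
#'   `c(num =, den =)` pair, plus `sens`/`spec` as doubles for convenience.
#' @examples
#' sens_spec(c(10, 10, 0, 0), c(TRUE, TRUE, FALSE, FALSE), 8)
#' @export
sens_spec <- function(scores, labels, threshold) {
  stopifnot(length(scores) == length(labels))
  labels <- as.logical(labels)
  if (!any(labels) || all(labels))
    stop("both outcome classes are required to compute sensitivity/specificity")
  pred <- scores > threshold
  tp <- sum(pred & labels); fn <- sum(!pred & labels)
  tn <- sum(!pred & !labels); fp <- sum(pred & !labels)
  list(sensitivity = rational(tp, tp + fn),
       specificity = rational(tn, tn + fp),
       sens = tp / (tp + fn), spec = tn / (tn + fp))
}

#' Youden-optimal integer threshold
#'
#' Enumerates integer thresholds 0..max(scores) and returns the one
#' maximizing Youden's J = sensitivity + specificity - 1 under the strict
#' `score > threshold` rule; ties are broken toward the lowest threshold.
#'
#' @inheritParams sens_spec
#' @param rule `"youden"`, or `"fixed:k"` to pin the threshold at integer k
#'   (e.g. `"fixed:8"`).
#' @return Integer threshold.
#' @export
best_threshold <- function(scores, labels, rule = "youden") {
  labels <- as.logical(labels)
  if (!any(labels) || all(labels))
    stop("both outcome classes are required to choose a threshold")
  if (startsWith(rule, "fixed:"))
    return(as.integer(sub("^fixed:", "", rule)))
  stopifnot(rule == "youden")
  cand <- 0:max(0L, max(scores))
  n_pos <- sum(labels); n_neg <- sum(!labels)
  # J = TP/n_pos + TN/n_neg - 1 has fixed denominators, so ranking by the
  # integer key TP*n_neg + TN*n_pos is exact
  key <- vapply(cand, function(thr) {
    pred <- scores > thr
    sum(pred & labels) * n_neg + sum(!pred & !labels) * n_pos
  }, numeric(1))
  cand[which.max(key)]  # which.max takes the first, i.e. lowest, maximizer
}

.default_feature_order <- c("ivh_high", "wmi_multiple_or_cystic", "ch_large",
                            "ivh_low", "wmi_isolated", "ch_small",
                            "ch_bilateral_bonus")

#' Configuration for the greedy weight search
#'
#' @param feature_order order in which the scored levels are escalated;
#'   default = descending clinical severity. Results are order-dependent,
#'   so the order is an explicit, recorded parameter.
#' @param max_weight per-level cap on the point value (guarantees
#'   termination).
#' @param threshold_rule threshold used to read off sensitivity/specificity
#'   at each iteration: `"youden"` (recomputed each iteration) or
#'   `"fixed:k"`.
#' @param start starting [weight_table()]; default [baseline_weights()].
#' @return A `search_config` list.
#' @export
search_config <- function(feature_order = .default_feature_order,
                          max_weight = 10L,
                          threshold_rule = "youden",
                          start = baseline_weights()) {
  if (!setequal(feature_order, .weight_levels) ||
      length(feature_order) != length(.weight_levels))
    stop("feature_order must cover every weighted level exactly once")
  stopifnot(max_weight >= 1L, inherits(start, "weight_table"))
  structure(list(feature_order = feature_order,
                 max_weight = as.integer(max_weight),
                 threshold_rule = threshold_rule, start = start),
            class = "search_config")
}

#' Learn integer score weights by greedy escalation
#'
#' Starting from the equal-weight baseline, the point value of one injury
#' feature at a time is repeatedly increased by one. After each proposal
#' the cohort is rescored, an operating threshold is chosen (Youden by
#' default), and the proposal is accepted while sensitivity strictly
#' increases and specificity does not decrease relative to the last
#' accepted state. At the first rejection (or the per-level cap) the search
#' moves to the next feature. Comparisons use exact rational arithmetic, so
#' subject order cannot affect the result; feature order can, and is part
#' of the configuration.
#'
#' @param cohort a labeled `ndi_cohort` (or any data frame that
#'   [score_injury()] accepts together with a logical `severe` column).
#' @param config a [search_config()].
#' @return List with `weights` (the learned [weight_table()]) and `trace`
#'   (a data frame with one row per proposal: feature, trial weight, chosen
#'   threshold, sensitivity, specificity, accepted).
#' @export
learn_weights <- function(cohort, config = search_config()) {
  stopifnot(inherits(config, "search_config"))
  df <- as.data.frame(cohort)
  if (!is.null(df$severe)) df <- df[!is.na(df$severe), , drop = FALSE]
  labels <- as.logical(df$severe)
  if (!any(labels) || all(labels))
    stop("cohort must contain both outcome classes")

  w <- unclass(config$start)
  eval_state <- function(weights) {
    s <- score_injury(df, restore_wt(weights))
    thr <- best_threshold(s, labels, config$threshold_rule)
    c(list(threshold = thr), sens_spec(s, labels, thr))
  }
  cur <- eval_state(w)
  trace <- list()
  for (feat in config$feature_order) {
    repeat {
      if (w[feat] >= config$max_weight) break
      trial <- w
      trial[feat] <- trial[feat] + 1L
      st <- eval_state(trial)
      ok <- rat_gt(st$sensitivity, cur$sensitivity) &&
        rat_ge(st$specificity, cur$specificity)
      trace[[length(trace) + 1L]] <- data.frame(
        feature = feat, trial_weight = trial[[feat]],
        threshold = st$threshold, sensitivity = st$sens,
        specificity = st$spec, accepted = ok)
      if (!ok) break
      w <- trial
      cur <- st
    }
  }
  # enforce within-domain severity ordering post hoc
  for (pair in list(c("ch_small", "ch_large"), c("ivh_low", "ivh_high"),
                    c("wmi_isolated", "wmi_multiple_or_cystic"))) {
    if (w[pair[2]] < w[pair[1]]) {
      warning("within-domain ordering was binding: raising ", pair[2],
              " from ", w[pair[2]], " to ", w[pair[1]])
      w[pair[2]] <- w[pair[1]]
    }
  }
  trace <- if (length(trace)) do.call(rbind, trace) else
    data.frame(feature = character(0), trial_weight = integer(0),
               threshold = integer(0), sensitivity = numeric(0),
               specificity = numeric(0), accepted = logical(0))
  rownames(trace) <- NULL
  list(weights = restore_wt(w), trace = trace,
       threshold = cur$threshold,
       sensitivity = cur$sens, specificity = cur$spec)
}

restore_wt <- function(w) {
  structure(as.integer(w), names = names(w), class = "weight_table")
}
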