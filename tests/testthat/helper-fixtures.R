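# Fixture builders used across the suite. Everything is generated in code;
# no data files.

# one full-schema cohort row with benign defaults, overridable per field
cohort_row <- function(id = "A1", ...) {
  row <- list(
    id = id, gestational_age = 27.0, birth_weight = 900, sga = 0, male = 1,
    race = "Caucasian", preeclampsia = 0, chorioamnionitis = 0,
    vaginal_delivery = 0, antenatal_steroids_any = 1,
    antenatal_steroids_complete = 1, antenatal_magnesium = 1, apgar5 = 7,
    postnatal_steroids = 0, ventilator_days = 5, bpd = 0, inotropes = 0,
    sepsis = 0, nec = 0, pda_ligation = 0, seizures = 0, severe_rop = 0,
    ivh_grade = "none", ch_size = "none", ch_bilateral = 0, wmi_lesions = 0,
    wmi_cystic = 0, bayley_cognitive = 95, bayley_motor = 95,
    bayley_language = 95)
  mods <- list(...)
  row[names(mods)] <- mods
  as.data.frame(row, stringsAsFactors = FALSE)
}

cohort_df <- function(...) do.call(rbind, list(...))

# minimal injury-only frame (accepted by score_injury / learn_weights)
injury_rows <- function(n, ivh = "none", ch = "none", bil = FALSE,
                        lesions = 0, cystic = FALSE, severe) {
  do.call(rbind, replicate(n, data.frame(
    ivh_grade = ivh, ch_size = ch, ch_bilateral = bil,
    wmi_lesions = lesions, wmi_cystic = cystic, severe = severe,
    stringsAsFactors = FALSE), simplify = FALSE))
}

# independent Table-1 arithmetic for the exhaustive scoring oracle:
# per-domain lookups summed directly, no call into score_injury
lookup_score <- function(ivh_grade, ch_size, ch_bilateral, lesions, cystic) {
  ivh <- c(none = 0, I = 2, II = 2, III = 5, IV = 5)[[ivh_grade]]
  ch <- c(none = 0, punctate_or_small = 1, large = 3)[[ch_size]]
  bil <- if (ch_bilateral) 1 else 0
  wmi <- if (cystic || lesions > 2) 5 else if (lesions >= 1) 2 else 0
  ivh + ch + bil + wmi
}

# brute-force AUC: concordant pairs + half ties over all pos/neg pairs
bruteforce_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# exhaustive two-sided Fisher p for a 2x2 table by hypergeometric
# enumeration with the point-probability criterion
enumerate_fisher_2x2 <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  obs <- stats::dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}
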