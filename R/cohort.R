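## Cohort schema: one row per infant. Booleans are stored 0/1 in CSV,
## logical in memory. The severe label is always derived from the Bayley
## scores, never read from a file.

.clinical_binary_cols <- c(
  "sga", "male", "preeclampsia", "chorioamnionitis", "vaginal_delivery",
  "antenatal_steroids_any", "antenatal_steroids_complete",
  "antenatal_magnesium", "postnatal_steroids", "bpd", "inotropes",
  "sepsis", "nec", "pda_ligation", "seizures", "severe_rop")

.cohort_cols <- c(
  "id", "gestational_age", "birth_weight", .clinical_binary_cols[1:2],
  "race", .clinical_binary_cols[3:8], "apgar5",
  .clinical_binary_cols[9], "ventilator_days", .clinical_binary_cols[10:16],
  "ivh_grade", "ch_size", "ch_bilateral", "wmi_lesions", "wmi_cystic",
  "bayley_cognitive", "bayley_motor", "bayley_language")

.race_levels <- c("African-American", "Asian", "Caucasian", "Hispanic")

#' Label severe neurodevelopmental impairment from Bayley-III scores
#'
#' An infant is labeled severe when any one Bayley-III composite (cognitive,
#' motor, language) lies more than two standard deviations below the
#' normative mean of 100, i.e. at or below 70; normal-moderate outcome
#' requires all three composites above 70.
#'
#' @param cognitive,motor,language Bayley-III composite scores (normative
#'   mean 100, SD 15; valid range 40--160). Vectorized.
#' @return Logical vector: `TRUE` = severe impairment. Any missing
#'   component is an error -- an infant without complete scores cannot be
#'   labeled and is excluded upstream.
#' @examples
#' label_severe(70, 100, 100)  # TRUE: one component at the cutoff
#' label_severe(71, 71, 71)    # FALSE: all components above 70
#' @export
label_severe <- function(cognitive, motor, language) {
  if (any(is.na(cognitive)) || any(is.na(motor)) || any(is.na(language)))
    stop("all three Bayley-III components are required to label an outcome")
  if (any(c(cognitive, motor, language) < 40) ||
      any(c(cognitive, motor, language) > 160))
    stop("Bayley-III composite scores must lie in [40, 160]")
  pmin(cognitive, motor, language) <= 70
}

#' Assemble and validate a cohort
#'
#' Takes a data frame in the cohort schema, validates every row, derives
#' the severe-outcome label, and returns a `ndi_cohort`. Rows violating an
#' invariant are reported together in a single error listing the offending
#' row numbers.
#'
#' @param df data frame with exactly the cohort columns (see
#'   [cohort_columns()]). Booleans as 0/1 or logical; missing Bayley scores
#'   as `NA` (all three or none).
#' @param provenance free-text source tag stored on the cohort.
#' @return A data frame of class `ndi_cohort` with typed columns, a logical
#'   `severe` column derived from the Bayley scores (`NA` when scores are
#'   absent), and a `provenance` attribute.
#' @export
as_cohort <- function(df, provenance = "unspecified") {
  stopifnot(is.data.frame(df))
  unknown <- setdiff(names(df), c(.cohort_cols, "severe"))
  if (length(unknown))
    stop("unknown column(s): ", paste(unknown, collapse = ", "))
  missing_cols <- setdiff(.cohort_cols, names(df))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  if ("severe" %in% names(df)) {
    warning("'severe' column in input is ignored; the label is derived ",
            "from the Bayley-III scores")
    df$severe <- NULL
  }
  df <- df[, .cohort_cols]
  df$id <- as.character(df$id)
  for (col in .clinical_binary_cols)
    df[[col]] <- as.logical(df[[col]])
  df$ch_bilateral <- as.logical(df$ch_bilateral)
  df$wmi_cystic <- as.logical(df$wmi_cystic)

  problems <- character(0)
  flag <- function(bad, msg) {
    if (any(bad, na.rm = TRUE))
      problems <<- c(problems,
                     paste0("row(s) ", paste(which(bad), collapse = ","),
                            ": ", msg))
  }
  dup <- duplicated(df$id) | duplicated(df$id, fromLast = TRUE)
  flag(dup, "duplicate id")
  flag(is.na(df$gestational_age) | df$gestational_age > 30,
       "gestational_age missing or > 30 weeks (cohort inclusion is <= 30)")
  flag(!is.na(df$gestational_age) & df$gestational_age < 20,
       "implausible gestational_age (< 20 weeks)")
  flag(is.na(df$birth_weight) | df$birth_weight <= 0,
       "birth_weight missing or non-positive")
  flag(!df$race %in% .race_levels, "unknown race category")
  flag(is.na(df$apgar5) | df$apgar5 < 0 | df$apgar5 > 10,
       "apgar5 outside 0..10")
  flag(is.na(df$ventilator_days) | df$ventilator_days < 0,
       "ventilator_days missing or negative")
  for (col in .clinical_binary_cols)
    flag(is.na(df[[col]]), paste0(col, " missing/not 0-1"))
  flag(!df$ivh_grade %in% c(0:4, "none", "I", "II", "III", "IV"),
       "ivh_grade not in 0..4")
  ch_ok <- !is.na(df$ch_size) &
    df$ch_size %in% c("none", "punctate", "small", "punctate_or_small", "large")
  flag(!ch_ok, "unknown ch_size")
  flag(ch_ok & df$ch_bilateral &
         df$ch_size == "none", "bilateral CH without a CH")
  flag(is.na(df$wmi_lesions) | df$wmi_lesions < 0 |
         df$wmi_lesions != round(df$wmi_lesions),
       "wmi_lesions not a non-negative integer")
  flag(df$wmi_cystic & df$wmi_lesions == 0,
       "cystic WMI with zero lesions (a cyst counts as a lesion)")
  bay <- df[, c("bayley_cognitive", "bayley_motor", "bayley_language")]
  n_missing <- rowSums(is.na(bay))
  flag(n_missing %in% 1:2,
       "incomplete Bayley-III scores (supply all three components or none)")
  in_range <- function(x) is.na(x) | (x >= 40 & x <= 160)
  flag(!(in_range(bay[[1]]) & in_range(bay[[2]]) & in_range(bay[[3]])),
       "Bayley-III composite outside [40, 160]")
  if (length(problems))
    stop("cohort validation failed:\n  ", paste(problems, collapse = "\n  "))

  df$ch_size <- vapply(df$ch_size, normalize_ch_size, character(1),
                       USE.NAMES = FALSE)
  df$ivh_grade <- vapply(df$ivh_grade, normalize_ivh_grade, character(1),
                         USE.NAMES = FALSE)
  df$wmi_lesions <- as.integer(df$wmi_lesions)
  df$severe <- ifelse(n_missing == 3L, NA,
                      pmin(bay[[1]], bay[[2]], bay[[3]]) <= 70)
  structure(df, class = c("ndi_cohort", "data.frame"),
            provenance = provenance)
}

#' Read a cohort CSV
#'
#' Reads and validates a cohort table. The file must have one header row
#' with exactly the documented columns; booleans coded 0/1; missing values
#' as empty cells; UTF-8. A `severe` column, if present, is ignored with a
#' warning: the label is always re-derived from the Bayley-III scores.
#'
#' @param path path to the CSV file.
#' @return A validated `ndi_cohort` (see [as_cohort()]).
#' @export
load_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(id = "character"))
  as_cohort(df, provenance = path)
}

#' Write a cohort to CSV
#'
#' Inverse of [load_cohort()] up to column order: booleans are written as
#' 0/1, missing Bayley scores as empty cells, and the derived `severe`
#' column is omitted (it is never stored).
#'
#' @param cohort an `ndi_cohort`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "ndi_cohort"))
  out <- as.data.frame(cohort)[, .cohort_cols]
  for (col in c(.clinical_binary_cols, "ch_bilateral", "wmi_cystic"))
    out[[col]] <- as.integer(out[[col]])
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Column names of the cohort CSV schema
#' @return Character vector of the required columns, in canonical order.
#' @export
cohort_columns <- function() .cohort_cols

#' Per-subject MRI scores for a cohort
#'
#' @param cohort an `ndi_cohort`.
#' @param weights a [weight_table()].
#' @return Integer vector of scores, one per row.
#' @export
cohort_scores <- function(cohort, weights = final_weights()) {
  stopifnot(inherits(cohort, "ndi_cohort"))
  score_injury(as.data.frame(cohort), weights)
}

#' Labeled subset of a cohort
#'
#' Drops records without Bayley-III scores (and hence without an outcome
#' label); errors if fewer than one record per outcome class remains.
#'
#' @param cohort an `ndi_cohort`.
#' @return The labeled `ndi_cohort`.
#' @export
labeled_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "ndi_cohort"))
  out <- cohort[!is.na(cohort$severe), , drop = FALSE]
  if (length(unique(out$severe)) < 2L)
    stop("labeled cohort must contain both outcome classes")
  out
}

#' @export
print.ndi_cohort <- function(x, ...) {
  n <- nrow(x)
  lab <- !is.na(x$severe)
  prov <- attr(x, "provenance")
  if (is.null(prov)) prov <- "unknown"
  cat(sprintf("<ndi_cohort> %d infants (%d labeled, %d severe) [%s]\n",
              n, sum(lab), sum(x$severe, na.rm = TRUE), prov))
  NextMethod()
}
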