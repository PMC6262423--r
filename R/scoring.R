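#' Construct an MRI injury profile
#'
#' One infant's term-equivalent MRI findings in the three injury domains:
#' intraventricular hemorrhage (IVH, Papile grade), cerebellar hemorrhage
#' (CH, size and laterality), and white matter injury (WMI, punctate lesion
#' count and cystic change).
#'
#' @param ivh_grade IVH grade: one of `"none"`, `"I"`, `"II"`, `"III"`,
#'   `"IV"` (Papile classification). Integer 0--4 is also accepted, with 0
#'   meaning no IVH.
#' @param ch_size cerebellar hemorrhage size: `"none"`,
#'   `"punctate_or_small"` (up to <50% of a cerebellar hemisphere; the
#'   synonyms `"punctate"` and `"small"` are accepted and merged), or
#'   `"large"` (>50% of a hemisphere).
#' @param ch_bilateral logical; bilateral cerebellar hemorrhage. Only
#'   meaningful when `ch_size != "none"`.
#' @param wmi_lesion_count non-negative integer count of punctate white
#'   matter lesions.
#' @param wmi_cystic logical; cystic white matter injury. A cystic flag
#'   with zero lesions is rejected: a cyst is itself a lesion.
#'
#' @return An object of class `injury_profile` (a named list of the five
#'   validated fields).
#' @examples
#' injury_profile(ivh_grade = "IV", ch_size = "none",
#'                ch_bilateral = FALSE, wmi_lesion_count = 0,
#'                wmi_cystic = FALSE)
#' @export
injury_profile <- function(ivh_grade = "none", ch_size = "none",
                           ch_bilateral = FALSE, wmi_lesion_count = 0L,
                           wmi_cystic = FALSE) {
  ivh_grade <- normalize_ivh_grade(ivh_grade)
  ch_size <- normalize_ch_size(ch_size)
  stopifnot(is.logical(ch_bilateral), length(ch_bilateral) == 1L,
            !is.na(ch_bilateral),
            is.logical(wmi_cystic), length(wmi_cystic) == 1L,
            !is.na(wmi_cystic))
  if (length(wmi_lesion_count) != 1L || is.na(wmi_lesion_count) ||
      wmi_lesion_count < 0 || wmi_lesion_count != round(wmi_lesion_count))
    stop("wmi_lesion_count must be a single non-negative integer")
  if (ch_bilateral && ch_size == "none")
    stop("ch_bilateral = TRUE requires a cerebellar hemorrhage (ch_size != 'none')")
  if (wmi_cystic && wmi_lesion_count < 1L)
    stop("wmi_cystic = TRUE requires wmi_lesion_count >= 1 (a cyst counts as a lesion)")
  structure(list(ivh_grade = ivh_grade, ch_size = ch_size,
                 ch_bilateral = ch_bilateral,
                 wmi_lesion_count = as.integer(wmi_lesion_count),
                 wmi_cystic = wmi_cystic),
            class = "injury_profile")
}

normalize_ivh_grade <- function(grade) {
  if (is.numeric(grade)) {
    if (length(grade) != 1L || is.na(grade) || !grade %in% 0:4)
      stop("numeric ivh_grade must be a single value in 0..4")
    return(c("none", "I", "II", "III", "IV")[grade + 1L])
  }
  grade <- as.character(grade)
  if (length(grade) == 1L && !is.na(grade) && grade %in% as.character(0:4))
    return(c("none", "I", "II", "III", "IV")[as.integer(grade) + 1L])
  if (length(grade) != 1L || is.na(grade) ||
      !grade %in% c("none", "I", "II", "III", "IV"))
    stop("unknown IVH grade label: ", deparse(grade))
  grade
}

normalize_ch_size <- function(size) {
  size <- as.character(size)
  if (length(size) != 1L || is.na(size))
    stop("ch_size must be a single string")
  if (size %in% c("punctate", "small")) size <- "punctate_or_small"
  if (!size %in% c("none", "punctate_or_small", "large"))
    stop("unknown ch_size label: ", deparse(size))
  size
}

#' Collapse an IVH grade to the scored category
#'
#' Papile grades are scored in three bands: no IVH, low-grade (I/II), and
#' high-grade (III/IV).
#'
#' @param grade IVH grade as for [injury_profile()] (vectorized).
#' @return Character vector in `{"none", "low", "high"}`.
#' @examples
#' classify_ivh("III")  # "high"
#' classify_ivh("II")   # "low"
#' @export
classify_ivh <- function(grade) {
  vapply(grade, function(g) {
    g <- normalize_ivh_grade(g)
    switch(g, none = "none", I = "low", II = "low", III = "high", IV = "high")
  }, character(1), USE.NAMES = FALSE)
}

#' Collapse white matter injury findings to the scored category
#'
#' WMI is scored as none, isolated punctate (1--2 lesions, no cysts), or
#' multiple punctate (>2 lesions) / cystic. Cystic change dominates the
#' lesion count.
#'
#' @param lesion_count non-negative integer vector of punctate lesion counts.
#' @param cystic logical vector; cystic WMI present.
#' @return Character vector in
#'   `{"none", "isolated_punctate", "multiple_or_cystic"}`.
#' @examples
#' classify_wmi(2, FALSE)  # "isolated_punctate"
#' classify_wmi(3, FALSE)  # "multiple_or_cystic"
#' classify_wmi(1, TRUE)   # "multiple_or_cystic"
#' @export
classify_wmi <- function(lesion_count, cystic) {
  if (any(is.na(lesion_count)) || any(lesion_count < 0))
    stop("lesion_count must be non-negative")
  ifelse(cystic | lesion_count > 2, "multiple_or_cystic",
         ifelse(lesion_count >= 1, "isolated_punctate", "none"))
}

.weight_levels <- c("ch_small", "ch_large", "ch_bilateral_bonus",
                    "ivh_low", "ivh_high", "wmi_isolated",
                    "wmi_multiple_or_cystic")

#' Construct an integer weight table for the MRI score
#'
#' A weight table assigns non-negative integer points to each scored injury
#' level; absent/none levels implicitly score 0. Within each domain the more
#' severe level must carry at least as many points as the milder one.
#'
#' @param ch_small,ch_large points for punctate/small (<50% of a cerebellar
#'   hemisphere) and large (>50%) cerebellar hemorrhage.
#' @param ch_bilateral_bonus additional points for bilateral cerebellar
#'   hemorrhage, added on top of the size points.
#' @param ivh_low,ivh_high points for low-grade (I/II) and high-grade
#'   (III/IV) intraventricular hemorrhage.
#' @param wmi_isolated,wmi_multiple_or_cystic points for isolated punctate
#'   (<=2 lesions) and multiple punctate (>2) or cystic white matter injury.
#' @return Named integer vector of class `weight_table` over the seven
#'   scored levels.
#' @seealso [final_weights()], [baseline_weights()], [score_injury()]
#' @export
weight_table <- function(ch_small, ch_large, ch_bilateral_bonus,
                         ivh_low, ivh_high,
                         wmi_isolated, wmi_multiple_or_cystic) {
  w <- c(ch_small = ch_small, ch_large = ch_large,
         ch_bilateral_bonus = ch_bilateral_bonus,
         ivh_low = ivh_low, ivh_high = ivh_high,
         wmi_isolated = wmi_isolated,
         wmi_multiple_or_cystic = wmi_multiple_or_cystic)
  if (any(is.na(w)) || any(w < 0) || any(w != round(w)))
    stop("all weights must be non-negative integers")
  if (w["ch_large"] < w["ch_small"])
    stop("within-domain ordering violated: ch_large < ch_small")
  if (w["ivh_high"] < w["ivh_low"])
    stop("within-domain ordering violated: ivh_high < ivh_low")
  if (w["wmi_multiple_or_cystic"] < w["wmi_isolated"])
    stop("within-domain ordering violated: wmi_multiple_or_cystic < wmi_isolated")
  structure(as.integer(w), names = names(w), class = "weight_table")
}

#' The final published weights of the MRI scoring system
#'
#' The weighting selected by the iterative sensitivity/specificity search on
#' the development cohort: large CH 3, punctate/small CH 1, bilateral CH +1,
#' high-grade IVH 5, low-grade IVH 2, multiple-punctate/cystic WMI 5,
#' isolated punctate WMI 2. The attainable total ranges from 0 (no injury)
#' to 14 (large bilateral CH + grade III/IV IVH + multiple/cystic WMI).
#'
#' @return A [weight_table()].
#' @export
final_weights <- function() {
  weight_table(ch_small = 1L, ch_large = 3L, ch_bilateral_bonus = 1L,
               ivh_low = 2L, ivh_high = 5L,
               wmi_isolated = 2L, wmi_multiple_or_cystic = 5L)
}

#' Equal-weight baseline scoring
#'
#' The starting point of the weight search: every injury feature scores 0
#' when absent and 1 when present. Under the default convention the scored
#' features are the four domains -- CH of any size, CH bilaterality, IVH of
#' any grade, WMI of any extent -- so both levels of each graded domain carry
#' 1 point and the per-profile maximum is 4. The alternative reading (each
#' of the seven weighted levels as its own feature) yields the identical
#' table, because only one level per domain can be active in a profile.
#'
#' @param convention `"domains"` (default) or `"levels"`; kept as an
#'   explicit argument because the feature granularity of the equal-weight
#'   baseline is a modelling choice, not a mathematical necessity.
#' @return A [weight_table()] with every scored level at 1 point.
#' @export
baseline_weights <- function(convention = c("domains", "levels")) {
  match.arg(convention)
  weight_table(ch_small = 1L, ch_large = 1L, ch_bilateral_bonus = 1L,
               ivh_low = 1L, ivh_high = 1L,
               wmi_isolated = 1L, wmi_multiple_or_cystic = 1L)
}

#' Score an injury profile
#'
#' The MRI score is the sum of the three domain scores: CH size points plus
#' the bilateral bonus, IVH category points, and WMI category points.
#'
#' @param profile an [injury_profile()], or a data frame with columns
#'   `ivh_grade`, `ch_size`, `ch_bilateral`, `wmi_lesion_count` (or
#'   `wmi_lesions`), `wmi_cystic` (one row per subject, vectorized).
#' @param weights a [weight_table()]; defaults to [final_weights()].
#' @return Integer score(s).
#' @examples
#' score_injury(injury_profile(ivh_grade = "IV"))  # 5
#' score_injury(injury_profile())                  # 0
#' @export
score_injury <- function(profile, weights = final_weights()) {
  stopifnot(inherits(weights, "weight_table"))
  if (inherits(profile, "injury_profile")) {
    ivh <- classify_ivh(profile$ivh_grade)
    ch <- profile$ch_size
    bil <- profile$ch_bilateral
    wmi <- classify_wmi(profile$wmi_lesion_count, profile$wmi_cystic)
  } else if (is.data.frame(profile)) {
    cnt <- if ("wmi_lesion_count" %in% names(profile))
      profile$wmi_lesion_count else profile$wmi_lesions
    ivh <- classify_ivh(profile$ivh_grade)
    ch <- vapply(profile$ch_size, normalize_ch_size, character(1),
                 USE.NAMES = FALSE)
    bil <- as.logical(profile$ch_bilateral)
    wmi <- classify_wmi(cnt, as.logical(profile$wmi_cystic))
  } else stop("profile must be an injury_profile or a data frame")

  ch_pts <- ifelse(ch == "large", weights["ch_large"],
                   ifelse(ch == "punctate_or_small", weights["ch_small"], 0L))
  bil_pts <- ifelse(bil, weights["ch_bilateral_bonus"], 0L)
  ivh_pts <- ifelse(ivh == "high", weights["ivh_high"],
                    ifelse(ivh == "low", weights["ivh_low"], 0L))
  wmi_pts <- ifelse(wmi == "multiple_or_cystic",
                    weights["wmi_multiple_or_cystic"],
                    ifelse(wmi == "isolated_punctate",
                           weights["wmi_isolated"], 0L))
  as.integer(ch_pts + bil_pts + ivh_pts + wmi_pts)
}

#' Maximum attainable score under a weight table
#' @param weights a [weight_table()].
#' @return Integer: the score of the worst possible profile.
#' @export
max_score <- function(weights = final_weights()) {
  as.integer(weights["ch_large"] + weights["ch_bilateral_bonus"] +
             weights["ivh_high"] + weights["wmi_multiple_or_cystic"])
}

#' Enumerate every valid injury profile
#'
#' All combinations of IVH grade (5) x CH size (3) x bilaterality (where
#' permitted) x WMI category, with one representative lesion count per WMI
#' category. Used for exhaustive checks of the scoring arithmetic.
#'
#' @return A data frame of profiles, one row each, with the columns
#'   [score_injury()] accepts.
#' @keywords internal
#' @export
enumerate_profiles <- function() {
  grid <- expand.grid(
    ivh_grade = c("none", "I", "II", "III", "IV"),
    ch_size = c("none", "punctate_or_small", "large"),
    ch_bilateral = c(FALSE, TRUE),
    wmi = c("none", "isolated_punctate", "multiple_or_cystic"),
    stringsAsFactors = FALSE)
  grid <- grid[!(grid$ch_bilateral & grid$ch_size == "none"), ]
  grid$wmi_lesion_count <- c(none = 0L, isolated_punctate = 2L,
                             multiple_or_cystic = 3L)[grid$wmi]
  grid$wmi_cystic <- FALSE
  grid$wmi <- NULL
  rownames(grid) <- NULL
  grid
}

#' Classify a score against an operating threshold
#'
#' Predicted severe iff `score > threshold` (strict inequality; the
#' published operating point is a score greater than 8).
#'
#' @param score integer score(s).
#' @param threshold integer threshold.
#' @return Logical vector.
#' @examples
#' classify_by_threshold(9, 8)  # TRUE
#' classify_by_threshold(8, 8)  # FALSE
#' @export
classify_by_threshold <- function(score, threshold) {
  stopifnot(all(score >= 0), length(threshold) == 1L, threshold >= 0)
  score > threshold
}

#' @export
print.weight_table <- function(x, ...) {
  cat("MRI injury score weights (points per level):\n")
  print(structure(as.integer(x), names = names(x)))
  cat("max attainable score:", max_score(x), "\n")
  invisible(x)
}
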