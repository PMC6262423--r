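#' Covariate sets for the clinical and composite risk models
#'
#' Three named specifications are built in. The `full` clinical model uses
#' the eight covariates selected for biological plausibility and univariate
#' association (p < 0.10): gestational age, birth weight, any antenatal
#' steroids, 5-min Apgar, postnatal steroids, ventilator days, inotrope
#' use, and severe ROP. The `slim` model is the parsimonious set retained
#' by backwards stepwise AIC selection: ventilator days, delivery mode
#' (vaginal), any antenatal steroids, severe ROP. The `composite` model
#' adds the MRI injury score to the slim set.
#'
#' @param name `"full"`, `"slim"`, or `"composite"`; or `"custom"` with an
#'   explicit covariate vector.
#' @param covariates character vector of covariates when `name = "custom"`.
#' @return A `model_spec` list with elements `name` and `covariates`.
#' @export
model_spec <- function(name = c("full", "slim", "composite", "custom"),
                       covariates = NULL) {
  name <- match.arg(name)
  covs <- switch(name,
    full = c("gestational_age", "birth_weight", "antenatal_steroids_any",
             "apgar5", "postnatal_steroids", "ventilator_days",
             "inotropes", "severe_rop"),
    slim = c("ventilator_days", "vaginal_delivery",
             "antenatal_steroids_any", "severe_rop"),
    composite = c("ventilator_days", "vaginal_delivery",
                  "antenatal_steroids_any", "severe_rop", "imaging_score"),
    custom = covariates)
  if (is.null(covs) || anyDuplicated(covs))
    stop("covariates must be a non-empty set without duplicates")
  if (name == "composite" && sum(covs == "imaging_score") != 1L)
    stop("composite spec must include imaging_score exactly once")
  structure(list(name = name, covariates = covs), class = "model_spec")
}

model_frame <- function(cohort, covariates, weights = final_weights()) {
  df <- as.data.frame(cohort)
  if ("imaging_score" %in% covariates && !"imaging_score" %in% names(df))
    df$imaging_score <- score_injury(df, weights)
  if (is.null(df$severe)) stop("cohort carries no outcome label")
  df <- df[!is.na(df$severe), , drop = FALSE]
  missing_cov <- setdiff(covariates, names(df))
  if (length(missing_cov))
    stop("covariate(s) not in cohort: ", paste(missing_cov, collapse = ", "))
  mf <- df[, c("severe", covariates), drop = FALSE]
  mf <- mf[stats::complete.cases(mf), , drop = FALSE]  # complete-case per model
  for (col in covariates)
    mf[[col]] <- as.numeric(mf[[col]])
  mf$severe <- as.logical(mf$severe)
  if (!any(mf$severe) || all(mf$severe))
    stop("both outcome classes are required to fit a model")
  mf
}

#' Fit a binary logistic risk model
#'
#' Maximum-likelihood logistic regression (IRLS via [stats::glm()]) of the
#' severe-outcome label on the covariates of a [model_spec()]. Continuous
#' covariates enter untransformed; the MRI injury score is computed with
#' the supplied weight table when the spec includes `imaging_score`.
#' Complete-case analysis per model: rows missing any spec covariate are
#' dropped.
#'
#' @param cohort a labeled `ndi_cohort`.
#' @param spec a [model_spec()].
#' @param weights [weight_table()] used to compute `imaging_score` when the
#'   spec requires it.
#' @param loglik_path logical; when `TRUE`, also record the log-likelihood
#'   after each IRLS iteration (obtained by refitting with an increasing
#'   iteration cap), so ascent can be verified.
#' @return A `ndi_model`: coefficients, covariance (inverse observed
#'   information), log-likelihood, AIC, McFadden and Nagelkerke pseudo-R2,
#'   per-covariate VIF, `n_used`, and the underlying `glm` fit.
#' @section Degenerate designs: perfect separation is detected (fitted
#'   probabilities numerically 0/1 with exploding coefficients) and raised
#'   as an error naming the worst covariate; rank-deficient designs
#'   (aliased coefficients) are refused, as are designs with exact linear
#'   dependence among covariates (infinite VIF).
#' @export
fit_logistic <- function(cohort, spec, weights = final_weights(),
                         loglik_path = FALSE) {
  stopifnot(inherits(spec, "model_spec"))
  mf <- model_frame(cohort, spec$covariates, weights)
  fml <- stats::as.formula(paste("severe ~",
                                 paste(spec$covariates, collapse = " + ")))
  fit <- suppressWarnings(
    stats::glm(fml, family = stats::binomial(), data = mf,
               control = stats::glm.control(epsilon = 1e-10, maxit = 100)))
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; aliased covariate(s): ",
         paste(bad, collapse = ", "))
  }
  p_hat <- stats::fitted(fit)
  if ((any(p_hat > 1 - 1e-8) || any(p_hat < 1e-8)) &&
      max(abs(stats::coef(fit)[-1])) > 15) {
    worst <- names(which.max(abs(stats::coef(fit)[-1])))
    stop("perfect (quasi-)separation detected; covariate with divergent ",
         "coefficient: ", worst)
  }
  n <- nrow(mf)
  ll <- as.numeric(stats::logLik(fit))
  ll0 <- as.numeric(stats::logLik(
    stats::glm(severe ~ 1, family = stats::binomial(), data = mf)))
  k <- length(stats::coef(fit))
  vifs <- if (length(spec$covariates) >= 2L)
    vif_design(mf[, spec$covariates, drop = FALSE]) else
      stats::setNames(rep(NA_real_, length(spec$covariates)),
                      spec$covariates)
  path <- NULL
  if (loglik_path) {
    path <- vapply(seq_len(fit$iter), function(m) {
      as.numeric(stats::logLik(suppressWarnings(
        stats::glm(fml, family = stats::binomial(), data = mf,
                   control = stats::glm.control(epsilon = 1e-10,
                                                maxit = m)))))
    }, numeric(1))
  }
  structure(list(
    spec = spec,
    coefficients = stats::coef(fit),
    vcov = stats::vcov(fit),
    loglik = ll, loglik_null = ll0,
    aic = 2 * k - 2 * ll,
    pseudo_r2 = c(
      mcfadden = 1 - ll / ll0,
      nagelkerke = (1 - exp(2 * (ll0 - ll) / n)) / (1 - exp(2 * ll0 / n))),
    vif = vifs, n_used = n, loglik_path = path,
    glm = fit), class = "ndi_model")
}

#' Variance inflation factors
#'
#' For each covariate, VIF = 1 / (1 - R2) from the ordinary least-squares
#' regression of that covariate on all the others (with intercept). Values
#' above 5 flag excessive collinearity; exact linear dependence yields an
#' infinite VIF and the model fit is refused.
#'
#' @param cohort a labeled `ndi_cohort` (or data frame).
#' @param spec a [model_spec()] with at least two covariates.
#' @param weights [weight_table()] for `imaging_score`, if needed.
#' @return Named numeric vector of VIFs.
#' @export
vif <- function(cohort, spec, weights = final_weights()) {
  stopifnot(inherits(spec, "model_spec"), length(spec$covariates) >= 2L)
  mf <- model_frame(cohort, spec$covariates, weights)
  vif_design(mf[, spec$covariates, drop = FALSE])
}

vif_design <- function(x) {
  x <- as.matrix(x)
  out <- vapply(seq_len(ncol(x)), function(j) {
    fit <- stats::lm.fit(cbind(1, x[, -j, drop = FALSE]), x[, j])
    rss <- sum(fit$residuals^2)
    tss <- sum((x[, j] - mean(x[, j]))^2)
    if (tss == 0) return(Inf)
    r2 <- 1 - rss / tss
    if (r2 > 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  stats::setNames(out, colnames(x))
}

#' Backwards stepwise selection by AIC
#'
#' Starting from the model containing every candidate covariate, the single
#' covariate whose removal lowers AIC the most is deleted, repeatedly,
#' until no deletion lowers AIC. Ties are broken deterministically by
#' dropping the covariate that appears latest in the candidate ordering.
#'
#' @param cohort a labeled `ndi_cohort`.
#' @param candidates character vector of candidate covariates; defaults to
#'   all collected clinical variables (race excluded: it describes the
#'   cohort and is not a model covariate).
#' @param weights [weight_table()] for `imaging_score`, if among the
#'   candidates.
#' @return The final fitted `ndi_model` (spec name `"custom"`), with the
#'   elimination order in `$dropped`.
#' @export
backward_stepwise_aic <- function(cohort, candidates = clinical_candidates(),
                                  weights = final_weights()) {
  current <- candidates
  # all candidates fit on the complete cases of the FULL candidate set, so
  # AICs along the path are comparable
  mf <- model_frame(cohort, candidates, weights)
  fit_set <- function(covs) {
    if (length(covs) == 0L)
      return(stats::glm(severe ~ 1, family = stats::binomial(), data = mf))
    suppressWarnings(stats::glm(
      stats::as.formula(paste("severe ~", paste(covs, collapse = " + "))),
      family = stats::binomial(), data = mf,
      control = stats::glm.control(epsilon = 1e-10, maxit = 100)))
  }
  cur_aic <- stats::AIC(fit_set(current))
  dropped <- character(0)
  while (length(current) > 0L) {
    trial_aic <- vapply(current, function(cov)
      stats::AIC(fit_set(setdiff(current, cov))), numeric(1))
    best <- min(trial_aic)
    if (best >= cur_aic - 1e-9) break
    # among ties for the best deletion, drop the covariate latest in order
    tied <- current[trial_aic <= best + 1e-9]
    drop_cov <- tied[length(tied)]
    current <- setdiff(current, drop_cov)
    dropped <- c(dropped, drop_cov)
    cur_aic <- stats::AIC(fit_set(current))
  }
  if (length(current) == 0L)
    stop("stepwise selection eliminated every candidate covariate")
  out <- fit_logistic(cohort, model_spec("custom", covariates = current),
                      weights)
  out$dropped <- dropped
  out
}

#' All collected clinical covariates (stepwise candidate pool)
#' @return Character vector of covariate names.
#' @export
clinical_candidates <- function() {
  c("gestational_age", "birth_weight", "sga", "male", "preeclampsia",
    "chorioamnionitis", "vaginal_delivery", "antenatal_steroids_any",
    "antenatal_steroids_complete", "antenatal_magnesium", "apgar5",
    "postnatal_steroids", "ventilator_days", "bpd", "inotropes", "sepsis",
    "nec", "pda_ligation", "seizures", "severe_rop")
}

#' Predict the probability of severe impairment for one subject
#'
#' Evaluates the fitted model at a subject's covariate values and returns
#' the predicted probability with its delta-method standard error:
#' se(p) = p (1 - p) * sqrt(x' Sigma x), where Sigma is the coefficient
#' covariance.
#'
#' @param model a fitted `ndi_model`.
#' @param subject named list / one-row data frame supplying every model
#'   covariate (for a composite model either an `imaging_score` entry or
#'   the injury columns from which it can be computed).
#' @param weights [weight_table()] used if `imaging_score` must be derived
#'   from injury columns.
#' @return List with `probability`, `se` and `linear_predictor`.
#' @examples
#' \dontrun{
#' predict_risk(fit, list(ventilator_days = 30, vaginal_delivery = 0,
#'                        antenatal_steroids_any = 1, severe_rop = 0,
#'                        imaging_score = 10))
#' }
#' @export
predict_risk <- function(model, subject, weights = final_weights()) {
  stopifnot(inherits(model, "ndi_model"))
  subject <- as.list(subject)
  covs <- model$spec$covariates
  if ("imaging_score" %in% covs && is.null(subject$imaging_score))
    subject$imaging_score <- score_injury(
      injury_profile(
        ivh_grade = subject$ivh_grade %||% "none",
        ch_size = subject$ch_size %||% "none",
        ch_bilateral = as.logical(subject$ch_bilateral %||% FALSE),
        wmi_lesion_count = subject$wmi_lesion_count %||%
          subject$wmi_lesions %||% 0L,
        wmi_cystic = as.logical(subject$wmi_cystic %||% FALSE)),
      weights)
  absent <- covs[!vapply(covs, function(cv)
    !is.null(subject[[cv]]) && !is.na(subject[[cv]]), logical(1))]
  if (length(absent))
    stop("missing covariate(s): ", paste(absent, collapse = ", "))
  x <- c(1, as.numeric(unlist(subject[covs])))
  lp <- sum(x * model$coefficients)
  p <- stats::plogis(lp)
  se <- p * (1 - p) * sqrt(drop(t(x) %*% model$vcov %*% x))
  list(probability = p, se = se, linear_predictor = lp)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-subject predicted probabilities for a cohort
#' @param model a fitted `ndi_model`.
#' @param cohort a labeled `ndi_cohort`.
#' @param weights [weight_table()] for `imaging_score`, if needed.
#' @return Numeric vector of probabilities aligned with the model frame
#'   rows (complete cases of the spec covariates).
#' @export
predict_cohort <- function(model, cohort, weights = final_weights()) {
  mf <- model_frame(cohort, model$spec$covariates, weights)
  as.numeric(stats::predict(model$glm, newdata = mf, type = "response"))
}

#' @export
print.ndi_model <- function(x, ...) {
  cat(sprintf("<ndi_model '%s'> n = %d, AIC = %.1f, R2(Nagelkerke) = %.3f, R2(McFadden) = %.3f\n",
              x$spec$name, x$n_used, x$aic, x$pseudo_r2["nagelkerke"],
              x$pseudo_r2["mcfadden"]))
  print(round(x$coefficients, 4))
  if (!all(is.na(x$vif)))
    cat("VIF:", paste(sprintf("%s=%.2f", names(x$vif), x$vif),
                      collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a fitted model to JSON
#'
#' Library-free schema (version 1): spec, coefficients, covariance,
#' log-likelihood, AIC, pseudo-R2, VIF, n_used.
#'
#' @param model a `ndi_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  obj <- list(schema_version = 1L,
              spec = list(name = model$spec$name,
                          covariates = model$spec$covariates),
              coefficients = as.list(model$coefficients),
              vcov = unname(as.matrix(model$vcov)),
              loglik = model$loglik, aic = model$aic,
              pseudo_r2 = as.list(model$pseudo_r2),
              vif = as.list(model$vif), n_used = model$n_used)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
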