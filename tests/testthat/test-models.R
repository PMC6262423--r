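# closed-form and simulation oracles for the logistic-model layer

test_that("intercept-only fit recovers the closed-form Bernoulli MLE", {
  coh <- simulate_cohort(seed = 2)  # 154 infants at the default prevalence
  n_sev <- sum(coh$severe)
  m <- fit_logistic(coh, model_spec("custom", covariates = "male"))
  m0 <- stats::glm(severe ~ 1, family = binomial(),
                   data = as.data.frame(labeled_cohort(coh)))
  expect_equal(unname(coef(m0)[1]), log(n_sev / (nrow(coh) - n_sev)),
               tolerance = 1e-8)
  # and the package fit reproduces glm on the same frame
  expect_equal(unname(m$coefficients),
               unname(coef(glm(severe ~ male, family = binomial(),
                               data = as.data.frame(coh)))),
               tolerance = 1e-8)
})

test_that("a single binary covariate's coefficient is the 2x2 log odds ratio", {
  set.seed(31)
  x <- rbinom(400, 1, 0.4)
  y <- rbinom(400, 1, plogis(-1 + 1.2 * x))
  df <- data.frame(x = x, severe = as.logical(y))
  class(df) <- c("ndi_cohort", "data.frame")
  m <- fit_logistic(df, model_spec("custom", covariates = "x"))
  tab <- table(x, y)
  lor <- log(tab["1", "1"] * tab["0", "0"] / (tab["1", "0"] * tab["0", "1"]))
  expect_equal(unname(m$coefficients["x"]), unname(lor), tolerance = 1e-6)
})

test_that("null labels give slope estimates near zero at large n", {
  set.seed(8)
  df <- data.frame(x1 = rnorm(4000), x2 = rbinom(4000, 1, 0.5),
                   severe = as.logical(rbinom(4000, 1, 0.3)))
  class(df) <- c("ndi_cohort", "data.frame")
  m <- fit_logistic(df, model_spec("custom", covariates = c("x1", "x2")))
  ses <- sqrt(diag(m$vcov))[-1]
  expect_true(all(abs(m$coefficients[-1]) < 3 * ses))
})

test_that("log-likelihood ascends across IRLS iterations", {
  coh <- simulate_cohort(seed = 4)
  for (name in c("full", "slim", "composite")) {
    m <- fit_logistic(coh, model_spec(name), loglik_path = TRUE)
    expect_true(all(diff(m$loglik_path) > -1e-8))
    expect_equal(m$loglik_path[length(m$loglik_path)], m$loglik,
                 tolerance = 1e-8)
  }
})

test_that("AIC, pseudo-R2 and n_used are populated and coherent", {
  coh <- simulate_cohort(seed = 4)
  m <- fit_logistic(coh, model_spec("slim"))
  expect_equal(m$aic, 2 * 5 - 2 * m$loglik, tolerance = 1e-10)
  expect_gt(m$pseudo_r2[["mcfadden"]], 0)
  expect_gt(m$pseudo_r2[["nagelkerke"]], m$pseudo_r2[["mcfadden"]])
  expect_lt(m$pseudo_r2[["nagelkerke"]], 1)
  expect_equal(m$n_used, nrow(labeled_cohort(coh)))
  expect_true(all(m$vif >= 1))
})

test_that("degenerate designs are refused with a named covariate", {
  set.seed(5)
  df <- data.frame(x = c(rep(0, 20), rep(1, 20)),
                   severe = c(rep(FALSE, 20), rep(TRUE, 20)))
  class(df) <- c("ndi_cohort", "data.frame")
  expect_error(fit_logistic(df, model_spec("custom", covariates = "x")),
               "separation.*x")
  df2 <- data.frame(x = rnorm(40), severe = rep(c(TRUE, FALSE), 20))
  df2$y <- 2 * df2$x  # exact linear dependence
  class(df2) <- c("ndi_cohort", "data.frame")
  expect_error(fit_logistic(df2, model_spec("custom",
                                            covariates = c("x", "y"))))
})

vif_from_frame <- function(x) {
  df <- as.data.frame(x)
  names(df) <- paste0("v", seq_len(ncol(df)))
  df$severe <- rep(c(TRUE, FALSE), length.out = nrow(df))
  class(df) <- c("ndi_cohort", "data.frame")
  vif(df, model_spec("custom", covariates = setdiff(names(df), "severe")))
}

test_that("VIF matches the 1/(1 - rho^2) closed form", {
  set.seed(12)
  n <- 500
  # near-orthogonal covariates
  x <- matrix(rnorm(3 * n), n)
  v <- vif_from_frame(x)
  expect_true(all(v < 1.1))
  # two correlated covariates: both VIFs equal 1/(1 - rho^2) exactly
  a <- rnorm(n); b <- 0.8 * a + sqrt(1 - 0.64) * rnorm(n)
  rho <- cor(a, b)
  v2 <- vif_from_frame(cbind(a, b))
  expect_equal(unname(v2), rep(1 / (1 - rho^2), 2), tolerance = 1e-9)
  # duplicated covariate: infinite VIF, fit refused
  df <- data.frame(a = a, b = a, severe = rep(c(TRUE, FALSE), n / 2))
  class(df) <- c("ndi_cohort", "data.frame")
  expect_true(all(is.infinite(
    vif(df, model_spec("custom", covariates = c("a", "b"))))))
})

test_that("backward stepwise drops pure-noise covariates and keeps the signal", {
  set.seed(21)
  n <- 2000
  x1 <- rnorm(n); x2 <- rbinom(n, 1, 0.5); noise <- rnorm(n)
  y <- rbinom(n, 1, plogis(-1 + 0.8 * x1 + 0.7 * x2))
  df <- data.frame(x1 = x1, x2 = x2, noise = noise, severe = as.logical(y))
  class(df) <- c("ndi_cohort", "data.frame")
  m <- backward_stepwise_aic(df, candidates = c("x1", "x2", "noise"))
  expect_setequal(m$spec$covariates, c("x1", "x2"))
  expect_equal(m$dropped, "noise")
  # a lone true generator is retained
  m2 <- backward_stepwise_aic(df, candidates = "x1")
  expect_equal(m2$spec$covariates, "x1")
})

test_that("greedy backward selection agrees with exhaustive AIC search when greedy-reachable", {
  set.seed(22)
  n <- 600
  df <- data.frame(a = rnorm(n), b = rbinom(n, 1, 0.5), c = rnorm(n),
                   d = rnorm(n))
  df$severe <- as.logical(rbinom(n, 1, plogis(-0.5 + df$a + 0.8 * df$b)))
  class(df) <- c("ndi_cohort", "data.frame")
  cand <- c("a", "b", "c", "d")
  m <- backward_stepwise_aic(df, candidates = cand)
  # exhaustive search over all 2^4 subsets
  subsets <- unlist(lapply(0:4, function(k)
    combn(cand, k, simplify = FALSE)), recursive = FALSE)
  aics <- sapply(subsets, function(s) {
    fml <- if (length(s)) paste("severe ~", paste(s, collapse = "+"))
           else "severe ~ 1"
    AIC(glm(as.formula(fml), family = binomial(), data = df))
  })
  best <- subsets[[which.min(aics)]]
  # greedy deletion can only be asserted against the global optimum when
  # the optimum is reachable by single deletions; here it is
  expect_setequal(m$spec$covariates, best)
})

test_that("predicted risk matches the inverse logit and the delta-method SE", {
  coh <- simulate_cohort(seed = 6)
  m <- fit_logistic(coh, model_spec("slim"))
  # all-zero covariates: probability = inverse-logit(intercept)
  pr <- predict_risk(m, list(ventilator_days = 0, vaginal_delivery = 0,
                             antenatal_steroids_any = 0, severe_rop = 0))
  expect_equal(pr$probability, plogis(m$coefficients[["(Intercept)"]]))
  expect_gte(pr$se, 0)
  expect_error(predict_risk(m, list(ventilator_days = 0)),
               "missing covariate.*vaginal_delivery")

  # delta-method SE within 10% of a parametric bootstrap from (beta, Sigma)
  subj <- list(ventilator_days = 20, vaginal_delivery = 1,
               antenatal_steroids_any = 1, severe_rop = 0)
  pr2 <- predict_risk(m, subj)
  x <- c(1, 20, 1, 1, 0)
  set.seed(99)
  draws <- MASS::mvrnorm(2000, m$coefficients, m$vcov)
  boot_se <- sd(plogis(draws %*% x))
  expect_equal(pr2$se, boot_se, tolerance = 0.10)
})

test_that("composite predictions can score injury columns on the fly", {
  coh <- simulate_cohort(seed = 6)
  m <- fit_logistic(coh, model_spec("composite"))
  a <- predict_risk(m, list(ventilator_days = 30, vaginal_delivery = 0,
                            antenatal_steroids_any = 1, severe_rop = 0,
                            ivh_grade = "IV", wmi_lesion_count = 1,
                            wmi_cystic = TRUE))
  b <- predict_risk(m, list(ventilator_days = 30, vaginal_delivery = 0,
                            antenatal_steroids_any = 1, severe_rop = 0,
                            imaging_score = 10))
  expect_equal(a$probability, b$probability)
  uninjured <- predict_risk(m, list(ventilator_days = 30,
                                    vaginal_delivery = 0,
                                    antenatal_steroids_any = 1,
                                    severe_rop = 0, imaging_score = 0))
  expect_gt(a$probability, uninjured$probability)
})

test_that("adding the imaging score to the slim model never lowers the log-likelihood", {
  for (seed in 1:5) {
    coh <- simulate_cohort(seed = seed)
    slim <- fit_logistic(coh, model_spec("slim"))
    comp <- fit_logistic(coh, model_spec("composite"))
    expect_gte(comp$loglik, slim$loglik - 1e-8)  # nested models
  }
})

test_that("stepwise-selected models beat the full model on AIC in most cohorts", {
  # the parsimonious model is, as in the source procedure, the product of
  # backwards stepwise AIC selection over all clinical candidates; under
  # the conditionally-independent generator it is that selected model (not
  # the fixed published covariate set) that carries the AIC advantage
  wins <- 0L; done <- 0L
  for (seed in 1:20) {
    coh <- simulate_cohort(seed = 100 + seed)
    full <- fit_logistic(coh, model_spec("full"))
    # rare binaries (e.g. seizures at ~5%) can quasi-separate a 154-infant
    # draw, which the fit rightly refuses; such seeds are not informative
    st <- tryCatch(backward_stepwise_aic(coh), error = function(e) NULL)
    if (is.null(st)) next
    done <- done + 1L
    if (st$aic < full$aic) wins <- wins + 1L
  }
  expect_gte(done, 15L)
  expect_gt(wins / done, 0.55)
})

test_that("composite-model coefficients are recovered as n grows", {
  # generative model: severe ~ plogis(-2.8 + 0.5 * score)
  for (n in c(500, 5000)) {
    coh <- simulate_from_score_model(n, beta = 0.5, intercept = -2.8,
                                     seed = 40 + n)
    m <- fit_logistic(coh, model_spec("custom", covariates = "imaging_score"))
    se <- sqrt(diag(m$vcov))
    expect_lt(abs(m$coefficients[["imaging_score"]] - 0.5),
              3 * se[["imaging_score"]])
    expect_lt(abs(m$coefficients[["(Intercept)"]] + 2.8),
              3 * se[["(Intercept)"]])
  }
})
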