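test_that("zero propensity coefficients give a balanced coin flip", {
  cfg <- sim_config(n_beneficiaries = 10000, seed = 1,
                    ps_coefficients = c("(Intercept)" = 0))
  sim <- simulate_cohort(cfg)
  frac <- mean(sim$cohort$treatment)
  expect_true(abs(frac - 0.5) < 3 * sqrt(0.25 / 10000))
  expect_true(all(sim$ground_truth$true_ps == 0.5))
})

test_that("no censoring means every long-term outcome is an event", {
  cfg <- sim_config(n_beneficiaries = 500, seed = 2,
                    censoring_spec = list(ltfu_rate = 0, study_end = Inf))
  sim <- simulate_cohort(cfg)
  expect_true(all(sim$cohort$event_long == 1))
  expect_equal(sim$cohort$time_long, sim$ground_truth$true_death_time)
})

test_that("the same config reproduces byte-identical tables", {
  cfg <- sim_config(n_beneficiaries = 300, seed = 7)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1$cohort, s2$cohort)
  expect_identical(s1$ground_truth, s2$ground_truth)
  c1 <- simulate_claims(cfg)
  c2 <- simulate_claims(cfg)
  expect_identical(c1$claims, c2$claims)
})

test_that("observed outcomes equal min(event, censoring) with matching indicator", {
  sim <- simulate_cohort(sim_config(n_beneficiaries = 2000, seed = 3))
  tr <- sim$ground_truth
  expect_equal(sim$cohort$time_long,
               pmin(tr$true_death_time, tr$true_censor_time_long))
  expect_equal(sim$cohort$event_long,
               as.integer(tr$true_death_time <= tr$true_censor_time_long))
  # coupling of the two outcomes
  expect_true(all(sim$cohort$time_short <= sim$cohort$time_long))
  expect_true(all(sim$cohort$event_long[sim$cohort$event_short == 1] == 1))
})

test_that("simulated marginals match the configured prevalences", {
  n <- 50000
  cfg <- sim_config(n_beneficiaries = n, seed = 11,
                    missingness_spec = list(covariates = 0))
  co <- simulate_cohort(cfg)$cohort
  prev <- cfg$covariate_spec$condition_prevalence
  for (cn in condition_names()) {
    p <- prev[[cn]]
    se <- sqrt(p * (1 - p) / n)
    expect_true(abs(mean(co[[cn]]) - p) <= 3 * se + 1e-12,
                label = sprintf("prevalence of %s", cn))
  }
  expect_true(abs(mean(co$sex == "male") - cfg$covariate_spec$male_prob) <=
                3 * sqrt(0.742 * 0.258 / n))
  expect_true(abs(mean(co$age) - 77) < 0.2)
})

test_that("logistic regression recovers the true propensity coefficients", {
  n <- 50000
  cfg <- sim_config(n_beneficiaries = n, seed = 13,
                    missingness_spec = list(covariates = 0))
  co <- simulate_cohort(cfg)$cohort
  x <- cbind(
    age = (co$age - 77) / 7.2,
    male = as.numeric(co$sex == "male"),
    race_black = as.numeric(co$race == "black"),
    race_other = as.numeric(co$race == "other"),
    chf = co$chf, cancer = co$cancer, renal_failure = co$renal_failure
  )
  # refit the full truth model so coefficients are comparable
  full <- cbind(x,
                do.call(cbind, lapply(2012:2015, function(y)
                  as.numeric(co$repair_year == y))),
                co$arrhythmia, co$coronary, co$diabetes, co$hypertension,
                co$copd, co$hyperlipidemia, co$rheumatoid_arthritis,
                co$prior_intact_aaa)
  colnames(full) <- c(colnames(x), paste0("year_", 2012:2015), "arrhythmia",
                      "coronary", "diabetes", "hypertension", "copd",
                      "hyperlipidemia", "rheumatoid_arthritis",
                      "prior_intact_aaa")
  fit <- glm(co$treatment ~ full, family = binomial)
  est <- coef(summary(fit))
  truth <- default_ps_coefficients()
  for (nm in names(truth)) {
    row <- if (nm == "(Intercept)") "(Intercept)" else paste0("full", nm)
    expect_true(abs(est[row, "Estimate"] - truth[[nm]]) <=
                  3 * est[row, "Std. Error"],
                label = sprintf("recovery of %s", nm))
  }
})

test_that("null treatment effect passes the log-rank test at nominal rate", {
  skip_if_not_installed("survival")
  null_cfg <- function(seed) {
    sim_config(n_beneficiaries = 250, seed = seed,
               missingness_spec = list(covariates = 0),
               survival_spec = list(long = list(log_hr = 0, beta = NULL),
                                    short = list(log_hr = 0, beta = NULL)),
               ps_coefficients = c("(Intercept)" = 0))
  }
  sig <- vapply(1:100, function(s) {
    co <- simulate_cohort(null_cfg(s))$cohort
    sd <- survival::survdiff(
      survival::Surv(co$time_long, co$event_long) ~ co$treatment
    )
    pchisq(sd$chisq, 1, lower.tail = FALSE) < 0.05
  }, logical(1))
  expect_gte(mean(!sig), 0.94)
})

test_that("claims carry planted ineligible records in configured numbers", {
  n <- 1000
  cfg <- sim_config(
    n_beneficiaries = n, seed = 5,
    missingness_spec = list(treatment_date = 0.05, covariates = 0),
    ineligible_spec = list(under65 = 0.01, conversion = 0, excluded_dx = 0,
                           excluded_proc = 0, short_enrollment = 0,
                           duplicates = 0)
  )
  sim <- simulate_claims(cfg)
  expect_equal(sum(is.na(sim$claims$treatment_date)), floor(0.05 * n))
  res <- apply_eligibility(sim$claims)
  log <- res$log
  expect_equal(log$n_excluded[log$criterion == "age under 65"], 10L)
  expect_equal(nrow(res$claims), n)
})

test_that("with no planted ineligibles every claim survives the filters", {
  cfg <- sim_config(
    n_beneficiaries = 200, seed = 6,
    missingness_spec = list(treatment_date = 0, covariates = 0),
    ineligible_spec = list(under65 = 0, conversion = 0, excluded_dx = 0,
                           excluded_proc = 0, short_enrollment = 0,
                           duplicates = 0)
  )
  sim <- simulate_claims(cfg)
  res <- apply_eligibility(sim$claims)
  expect_equal(nrow(res$claims), nrow(sim$claims))
  expect_true(all(res$log$n_excluded == 0))
})

test_that("configuration validation rejects bad inputs", {
  expect_error(sim_config(n_beneficiaries = 0), "positive")
  expect_error(sim_config(covariate_spec = list(male_prob = 1.4)), "0, 1")
  expect_error(sim_config(survival_spec = list(long = list(shape0 = -1))),
               "positive")
  expect_error(sim_config(ps_coefficients = c(bogus = 1)), "unknown")
})

test_that("YAML code lists override defaults key by key", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("rupture_dx: [I71.3]",
               "conditions:",
               "  chf: [I50.9, I50.1]"), path)
  codes <- read_code_lists(path)
  expect_equal(codes$rupture_dx, "I71.3")
  expect_equal(codes$conditions$chf, c("I50.9", "I50.1"))
  expect_equal(codes$evar_proc, default_code_lists()$evar_proc)
})
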