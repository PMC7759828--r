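# Simulation configuration for the synthetic claims generator.

#' Names of the 20 binary medical-condition covariates
#'
#' The baseline comorbidity set used throughout the package: congestive heart
#' failure through prior intact-aneurysm diagnosis. These are the covariates a
#' claims-based aortic-repair cohort adjusts for, and the synthetic generator
#' simulates each as an independent Bernoulli flag.
#'
#' @return Character vector of length 20.
#' @export
condition_names <- function() {
  c(
    "chf", "arrhythmia", "valvular", "coronary", "diabetes",
    "hypertension", "copd", "lower_extremity_vascular",
    "renal_atherosclerosis", "vascular_intestine", "renal_failure",
    "other_renal", "kidney_transplant", "liver_disease", "cerebrovascular",
    "other_neurological", "hyperlipidemia", "cancer", "rheumatoid_arthritis",
    "prior_intact_aaa"
  )
}

# Default condition prevalences: pooled arm prevalences of the study cohort
# the generator emulates (rare conditions stay rare).
default_condition_prevalence <- function() {
  setNames(
    c(0.0975, 0.1321, 0.0474, 0.1738, 0.0747, 0.2975, 0.1649, 0.0068,
      0.0060, 0.0012, 0.1087, 0.0005, 0.0009, 0.0081, 0.0204, 0.0341,
      0.1921, 0.0280, 0.0147, 0.1215),
    condition_names()
  )
}

#' Default code-list configuration
#'
#' Maps eligibility concepts and medical conditions to claim code strings.
#' The defaults are synthetic stand-in codes (`"DX_RUPT"`, `"PROC_EVAR"`,
#' ...); real ICD-9-CM code lists can be dropped in via the same structure
#' (each entry a character vector of codes).
#'
#' @return Named list with entries `rupture_dx`, `evar_proc`, `oar_proc`,
#'   `excluded_dx`, `excluded_proc`, and `conditions` (a named list mapping
#'   each condition covariate to its diagnosis codes).
#' @export
default_code_lists <- function() {
  list(
    rupture_dx = "DX_RUPT",
    evar_proc = "PROC_EVAR",
    oar_proc = "PROC_OAR",
    # thoracic/thoracoabdominal aneurysm, dissection
    excluded_dx = c("DX_THORACIC", "DX_THORACOABD", "DX_DISSECT"),
    # thoracic repair, visceral or renal bypass
    excluded_proc = c("PROC_THORACIC_REPAIR", "PROC_VISCERAL_BYPASS",
                      "PROC_RENAL_BYPASS"),
    conditions = setNames(
      as.list(paste0("DX_", toupper(condition_names()))),
      condition_names()
    )
  )
}

# Default true propensity coefficients on the encoded design (reference
# levels: white race, year 2011). Mildly confounded: the endovascular arm is
# older and carries more comorbidity, and uptake grows over calendar time.
default_ps_coefficients <- function() {
  c(
    "(Intercept)" = -0.70, age = 0.12, male = 0.12,
    race_black = 0.30, race_other = -0.05,
    year_2012 = 0.10, year_2013 = 0.25, year_2014 = 0.45, year_2015 = 0.60,
    chf = 0.45, arrhythmia = 0.30, coronary = 0.25, diabetes = 0.25,
    hypertension = 0.15, copd = 0.20, renal_failure = 0.35,
    hyperlipidemia = 0.20, cancer = 0.40, rheumatoid_arthritis = 0.60,
    prior_intact_aaa = 0.15
  )
}

# Default covariate effects on the log hazard (shared by both outcomes).
default_survival_beta <- function() {
  c(age = 0.30, male = 0.10, chf = 0.30, copd = 0.20,
    renal_failure = 0.25, cancer = 0.30)
}

#' Build a simulation configuration
#'
#' Assembles and validates the configuration object consumed by
#' [simulate_cohort()] and [simulate_claims()]. Defaults emulate the claims
#' cohort the package targets: mean age 77, predominantly white male, 20
#' binary comorbidities at their cohort prevalences, treatment uptake rising
#' over the 2011--2015 enrolment window, confounded treatment assignment
#' through a known logistic propensity model, per-arm Weibull event times
#' with a configurable treatment log-hazard effect, exponential loss to
#' follow-up, and administrative censoring at the study end date. The time
#' unit is days throughout.
#'
#' @param n_beneficiaries Number of eligible subjects to generate.
#' @param seed Integer seed; together with the other fields it fully
#'   determines the generated tables.
#' @param covariate_spec List with `age_mean`, `age_sd`, `male_prob`,
#'   `race_probs` (named: white/black/other), `year_probs` (named:
#'   2011--2015), `condition_prevalence` (named over [condition_names()]).
#' @param ps_coefficients Named vector of true log-odds coefficients for
#'   treatment assignment on the encoded design (see
#'   [default_ps_coefficients()] for the recognised names). Age enters
#'   standardized by the configured mean/sd.
#' @param survival_spec Per-outcome list (`long`, `short`), each with Weibull
#'   `shape0`/`scale0` (control arm baseline), optional `shape1`/`scale1`
#'   (treated baseline; defaults to the control values, giving proportional
#'   hazards), `log_hr` (treatment log-hazard effect applied on top of the
#'   baselines), and `beta` (named covariate log-hazard effects). `short`
#'   additionally has `horizon`, the administrative censoring time in days
#'   for the perioperative outcome.
#' @param censoring_spec List with `ltfu_rate` (exponential loss-to-follow-up
#'   hazard per day), `enrollment_start`/`enrollment_end` (calendar window
#'   for treatment dates) and `study_end` (administrative end of follow-up).
#' @param missingness_spec List with `treatment_date` (fraction of claims
#'   with a blanked treatment date) and `covariates` (fraction of cohort rows
#'   with one missing covariate).
#' @param ineligible_spec Named fractions of `n_beneficiaries` planted as
#'   additional ineligible claims: `under65`, `conversion`, `excluded_dx`,
#'   `excluded_proc`, `short_enrollment`, and `duplicates` (extra later
#'   claims for already-eligible beneficiaries).
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_beneficiaries = 1000L,
                       seed = 1L,
                       covariate_spec = list(),
                       ps_coefficients = default_ps_coefficients(),
                       survival_spec = list(),
                       censoring_spec = list(),
                       missingness_spec = list(),
                       ineligible_spec = list()) {
  if (length(n_beneficiaries) != 1L || !is.finite(n_beneficiaries) ||
      n_beneficiaries < 1) {
    abort("`n_beneficiaries` must be a positive integer.")
  }

  cov_default <- list(
    age_mean = 77, age_sd = 7.2, male_prob = 0.742,
    race_probs = c(white = 0.9139, black = 0.0548, other = 0.0313),
    year_probs = c(`2011` = 0.2327, `2012` = 0.2277, `2013` = 0.2050,
                   `2014` = 0.1965, `2015` = 0.1381),
    condition_prevalence = default_condition_prevalence()
  )
  covariate_spec <- utils::modifyList(cov_default, covariate_spec)

  surv_default <- list(
    long = list(shape0 = 1.1, scale0 = 3400, shape1 = NULL, scale1 = NULL,
                log_hr = log(0.8), beta = default_survival_beta()),
    short = list(shape0 = 0.8, scale0 = 85, shape1 = NULL, scale1 = NULL,
                 log_hr = log(0.55), beta = default_survival_beta(),
                 horizon = 35)
  )
  survival_spec <- utils::modifyList(surv_default, survival_spec)

  cens_default <- list(
    ltfu_rate = 5e-5,
    enrollment_start = as.Date("2011-01-01"),
    enrollment_end = as.Date("2015-09-30"),
    study_end = as.Date("2019-06-30")
  )
  censoring_spec <- utils::modifyList(cens_default, censoring_spec)
  censoring_spec$enrollment_start <- as.Date(censoring_spec$enrollment_start)
  censoring_spec$enrollment_end <- as.Date(censoring_spec$enrollment_end)
  if (!(is.numeric(censoring_spec$study_end) &&
        all(is.infinite(censoring_spec$study_end)))) {
    censoring_spec$study_end <- as.Date(censoring_spec$study_end)
  }

  miss_default <- list(treatment_date = 0.0535, covariates = 0.002)
  missingness_spec <- utils::modifyList(miss_default, missingness_spec)

  inel_default <- list(under65 = 0.02, conversion = 0.01, excluded_dx = 0.01,
                       excluded_proc = 0.01, short_enrollment = 0.01,
                       duplicates = 0.02)
  ineligible_spec <- utils::modifyList(inel_default, ineligible_spec)

  # -- validation ------------------------------------------------------------
  assert_probability(covariate_spec$male_prob, "male_prob")
  assert_probability(covariate_spec$race_probs, "race_probs")
  assert_probability(covariate_spec$year_probs, "year_probs")
  assert_probability(covariate_spec$condition_prevalence,
                     "condition_prevalence")
  if (abs(sum(covariate_spec$race_probs) - 1) > 1e-8) {
    abort("`race_probs` must sum to 1.")
  }
  if (abs(sum(covariate_spec$year_probs) - 1) > 1e-8) {
    abort("`year_probs` must sum to 1.")
  }
  missing_cond <- setdiff(condition_names(),
                          names(covariate_spec$condition_prevalence))
  if (length(missing_cond) > 0) {
    abort(paste0("condition_prevalence is missing: ",
                 paste(missing_cond, collapse = ", ")))
  }
  for (oc in c("long", "short")) {
    sp <- survival_spec[[oc]]
    assert_positive(sp$shape0, paste0(oc, "$shape0"))
    assert_positive(sp$scale0, paste0(oc, "$scale0"))
    if (!is.null(sp$shape1)) assert_positive(sp$shape1, paste0(oc, "$shape1"))
    if (!is.null(sp$scale1)) assert_positive(sp$scale1, paste0(oc, "$scale1"))
  }
  if (censoring_spec$ltfu_rate < 0) abort("`ltfu_rate` must be >= 0.")
  assert_probability(unlist(missingness_spec), "missingness_spec")
  assert_probability(unlist(ineligible_spec), "ineligible_spec")
  known_ps <- c("(Intercept)", "age", "male", "race_black", "race_other",
                paste0("year_", 2012:2015), condition_names())
  bad <- setdiff(names(ps_coefficients), known_ps)
  if (length(bad) > 0) {
    abort(paste0("unknown ps_coefficients: ", paste(bad, collapse = ", ")))
  }

  structure(
    list(
      n_beneficiaries = as.integer(n_beneficiaries),
      seed = as.integer(seed),
      covariate_spec = covariate_spec,
      ps_coefficients = ps_coefficients,
      survival_spec = survival_spec,
      censoring_spec = censoring_spec,
      missingness_spec = missingness_spec,
      ineligible_spec = ineligible_spec
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  n_beneficiaries:", x$n_beneficiaries, " seed:", x$seed, "\n")
  cat("  enrollment:", format(x$censoring_spec$enrollment_start), "to",
      format(x$censoring_spec$enrollment_end),
      "; study end:", format(x$censoring_spec$study_end), "\n")
  cat("  long-term treatment log-HR:", x$survival_spec$long$log_hr,
      " short-term:", x$survival_spec$short$log_hr, "\n")
  invisible(x)
}

# Linear predictor of the true propensity model on the generator's encoding.
true_ps_linpred <- function(cohort, config) {
  co <- config$ps_coefficients
  cs <- config$covariate_spec
  lp <- rep(co[["(Intercept)"]] %g0% 0, nrow(cohort))
  get_co <- function(nm) if (nm %in% names(co)) co[[nm]] else 0
  lp <- lp + get_co("age") * (cohort$age - cs$age_mean) / cs$age_sd
  lp <- lp + get_co("male") * (cohort$sex == "male")
  lp <- lp + get_co("race_black") * (cohort$race == "black")
  lp <- lp + get_co("race_other") * (cohort$race == "other")
  for (yr in 2012:2015) {
    lp <- lp + get_co(paste0("year_", yr)) * (cohort$repair_year == yr)
  }
  for (cn in condition_names()) {
    lp <- lp + get_co(cn) * cohort[[cn]]
  }
  lp
}

# Covariate log-hazard contribution for one outcome's survival spec.
survival_linpred <- function(cohort, beta, config) {
  cs <- config$covariate_spec
  lp <- rep(0, nrow(cohort))
  if (is.null(beta)) return(lp)
  for (nm in names(beta)) {
    lp <- lp + beta[[nm]] * switch(nm,
      age = (cohort$age - cs$age_mean) / cs$age_sd,
      male = as.numeric(cohort$sex == "male"),
      race_black = as.numeric(cohort$race == "black"),
      race_other = as.numeric(cohort$race == "other"),
      cohort[[nm]]
    )
  }
  lp
}

#' Read a code-list configuration from a YAML file
#'
#' The file mirrors [default_code_lists()]: top-level keys `rupture_dx`,
#' `evar_proc`, `oar_proc`, `excluded_dx`, `excluded_proc` (each a string
#' or list of strings) and a `conditions` mapping from condition name to
#' its diagnosis codes. Missing keys fall back to the defaults, so a
#' partial file overrides only what it names (e.g. dropping in real
#' ICD-9-CM lists).
#'
#' @param path YAML file path.
#' @return A code-list configuration list.
#' @export
read_code_lists <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- utils::modifyList(default_code_lists(), raw)
  out$conditions <- utils::modifyList(default_code_lists()$conditions,
                                      raw$conditions %||% list())
  out
}
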