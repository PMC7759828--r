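# Synthetic cohort and claims generator with known ground truth.

# Draw a Weibull event time with covariate effects on the log hazard:
# H(t) = (t / scale)^shape * exp(lp), so T = scale * (E / exp(lp))^(1/shape)
# with E ~ Exp(1). `shape`/`scale` may be vectors (per subject).
rweibull_ph <- function(n, shape, scale, lp) {
  e <- rexp(n)
  scale * (e / exp(lp))^(1 / shape)
}

simulate_arm_times <- function(cohort, treated, spec, config) {
  shape1 <- spec$shape1 %||% spec$shape0
  scale1 <- spec$scale1 %||% spec$scale0
  shape <- ifelse(treated, shape1, spec$shape0)
  scale <- ifelse(treated, scale1, spec$scale0)
  lp <- survival_linpred(cohort, spec$beta, config) +
    spec$log_hr * as.numeric(treated)
  rweibull_ph(nrow(cohort), shape, scale, lp)
}

#' Simulate an analysis-ready cohort with known ground truth
#'
#' Generates `n` subjects with baseline covariates drawn from the configured
#' marginals, confounded binary treatment assignment
#' `Z ~ Bernoulli(expit(beta . X))` under the configured true propensity
#' model, and a single death time with a piecewise hazard: a high-hazard
#' perioperative segment (the `short` Weibull, truncated at its horizon)
#' followed by the `long` Weibull for later mortality, each segment with
#' arm-specific shape/scale plus the configured treatment log-hazard effect.
#' Censoring combines exponential loss to follow-up with administrative
#' censoring at the study end; the short-term outcome is additionally
#' censored at the perioperative horizon. Observed outcomes follow the
#' right-censoring convention `Y = min(T, C)`, `d = I(T <= C)`, so the
#' short-term time never exceeds the long-term time and a perioperative
#' death is always a long-term event.
#'
#' @param config A [sim_config()] object.
#' @return A list with two tibbles:
#' \describe{
#'   \item{cohort}{one row per subject: id, treatment arm, covariates,
#'     `time_short`/`event_short`, `time_long`/`event_long`, `ipt_weight`
#'     (initialised to 1), and `treatment_date`.}
#'   \item{ground_truth}{the generating quantities per subject: true
#'     propensity score, true event and censoring times for both outcomes,
#'     and the true treatment log-hazard effects.}
#' }
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_beneficiaries
  cs <- config$covariate_spec
  cens <- config$censoring_spec

  with_seed(config$seed, {
    year <- sample(names(cs$year_probs), n, replace = TRUE,
                   prob = cs$year_probs)
    # treatment date uniform within the drawn repair year, clipped to the
    # enrolment window (2015 only runs through the window end).
    t_date <- as.Date(vapply(year, function(y) {
      lo <- max(as.Date(paste0(y, "-01-01")), cens$enrollment_start)
      hi <- min(as.Date(paste0(y, "-12-31")), cens$enrollment_end)
      as.numeric(lo) + floor(runif(1) * (as.numeric(hi) - as.numeric(lo) + 1))
    }, numeric(1)), origin = "1970-01-01")

    cohort <- tibble(
      subject_id = sprintf("S%06d", seq_len(n)),
      age = pmax(65, round(rnorm(n, cs$age_mean, cs$age_sd), 1)),
      sex = ifelse(rbinom(n, 1, cs$male_prob) == 1, "male", "female"),
      race = sample(names(cs$race_probs), n, replace = TRUE,
                    prob = cs$race_probs),
      repair_year = as.integer(year),
      treatment_date = t_date
    )
    for (cn in condition_names()) {
      cohort[[cn]] <- rbinom(n, 1, cs$condition_prevalence[[cn]])
    }

    lp_ps <- true_ps_linpred(cohort, config)
    true_ps <- expit(lp_ps)
    z <- rbinom(n, 1, true_ps)
    cohort$treatment <- z

    # One death process with a piecewise hazard: a high-hazard perioperative
    # segment (the `short` Weibull, up to its horizon) followed by the
    # `long` Weibull for later mortality. When both segments carry the same
    # treatment and covariate effects the conditional hazard is exactly
    # proportional between arms; arm-specific shapes give a non-PH regime.
    horizon <- config$survival_spec$short$horizon
    t_early <- simulate_arm_times(cohort, z == 1,
                                  config$survival_spec$short, config)
    t_late <- simulate_arm_times(cohort, z == 1,
                                 config$survival_spec$long, config)
    t_death <- ifelse(t_early <= horizon, t_early, horizon + t_late)

    admin_long <- if (is.numeric(cens$study_end) &&
                      all(is.infinite(cens$study_end))) {
      rep(Inf, n)
    } else {
      as.numeric(cens$study_end - cohort$treatment_date)
    }
    c_ltfu <- if (cens$ltfu_rate > 0) rexp(n, cens$ltfu_rate) else rep(Inf, n)
    c_long <- pmin(c_ltfu, admin_long)
    c_short <- pmin(c_long, horizon)

    cohort$time_long <- pmin(t_death, c_long)
    cohort$event_long <- as.integer(t_death <= c_long)
    cohort$time_short <- pmin(t_death, c_short)
    cohort$event_short <- as.integer(t_death <= c_short)
    cohort$ipt_weight <- 1

    # plant missing covariates (one random covariate per affected row)
    n_miss <- floor(config$missingness_spec$covariates * n)
    if (n_miss > 0) {
      rows <- sample.int(n, n_miss)
      cols <- sample(c("race", condition_names()), n_miss, replace = TRUE)
      for (k in seq_len(n_miss)) {
        cohort[rows[k], cols[k]] <- NA
      }
    }

    truth <- tibble(
      subject_id = cohort$subject_id,
      true_ps = true_ps,
      true_death_time = t_death,
      true_censor_time_long = c_long,
      true_censor_time_short = c_short,
      true_log_hr_long = config$survival_spec$long$log_hr,
      true_log_hr_short = config$survival_spec$short$log_hr
    )

    list(cohort = cohort, ground_truth = truth)
  })
}

# Build one claim row from a cohort row.
claim_from_subject <- function(row, codes, proc, extra_dx = character(),
                               extra_proc = character(),
                               enroll_back_days = 600) {
  cond_dx <- unlist(codes$conditions[condition_names()[
    unlist(row[condition_names()]) == 1 &
      !is.na(unlist(row[condition_names()]))
  ]], use.names = FALSE)
  dx <- unique(c(codes$rupture_dx, cond_dx, extra_dx))
  admission <- row$treatment_date - sample(0:1, 1)
  discharge <- admission + 1 + rpois(1, 6)
  tibble(
    beneficiary_id = row$subject_id,
    admission_date = admission,
    discharge_date = discharge,
    treatment_date = row$treatment_date,
    age_at_admission = row$age,
    sex = row$sex,
    race = row$race,
    enrollment_start = admission - enroll_back_days,
    diagnosis_codes = paste(dx[seq_len(min(length(dx), 25L))],
                            collapse = ";"),
    procedure_codes = paste(unique(c(proc, extra_proc)), collapse = ";")
  )
}

#' Simulate claims-level records
#'
#' Wraps each [simulate_cohort()] subject into an inpatient-claim record
#' (admission/discharge dates, diagnosis and procedure code strings,
#' demographics, enrolment and death dates) and plants additional ineligible
#' records covering every exclusion criterion the assembly stage checks:
#' under-65 admissions, conversion cases carrying both repair procedure code
#' sets, concurrent excluded diagnoses and procedures, short prior enrolment,
#' and duplicate later claims for eligible beneficiaries. A configured
#' fraction of eligible treatment dates is blanked (exactly
#' `floor(frac * n)` of them).
#'
#' Code columns hold `";"`-separated code strings; dates are ISO-8601.
#'
#' @param config A [sim_config()] object.
#' @param codes Code-list configuration, see [default_code_lists()].
#' @return A list with tibbles `claims`, `cohort` (the underlying eligible
#'   cohort) and `ground_truth`.
#' @export
simulate_claims <- function(config, codes = default_code_lists()) {
  stopifnot(inherits(config, "sim_config"))
  sim <- simulate_cohort(config)
  cohort <- sim$cohort
  n <- nrow(cohort)
  cens <- config$censoring_spec

  with_seed(config$seed + 1L, {
    proc <- ifelse(cohort$treatment == 1, codes$evar_proc[1], codes$oar_proc[1])
    claims <- purrr::map(seq_len(n), function(i) {
      claim_from_subject(cohort[i, ], codes, proc[i],
                         enroll_back_days = sample(400:2000, 1))
    }) |> bind_rows()

    # death / loss-to-follow-up dates consistent with the cohort outcomes
    died <- cohort$event_long == 1
    claims$death_date <- as.Date(ifelse(
      died, cohort$treatment_date + round(cohort$time_long), NA
    ), origin = "1970-01-01")
    lost <- !died & cohort$time_long <
      as.numeric(cens$study_end - cohort$treatment_date) - 0.5
    claims$enrollment_end <- as.Date(ifelse(
      lost, cohort$treatment_date + round(cohort$time_long), NA
    ), origin = "1970-01-01")

    # blank exactly floor(frac * n) treatment dates among eligible claims
    n_blank <- floor(config$missingness_spec$treatment_date * n)
    if (n_blank > 0) {
      claims$treatment_date[sample.int(n, n_blank)] <- as.Date(NA)
    }

    # ---- planted ineligible records ---------------------------------------
    inel <- config$ineligible_spec
    planted <- list()
    plant_base <- function(k, prefix) {
      if (k == 0) return(NULL)
      idx <- sample.int(n, k, replace = TRUE)
      rows <- cohort[idx, ]
      rows$subject_id <- sprintf("%s%05d", prefix, seq_len(k))
      rows
    }

    k <- floor(inel$under65 * n)
    if (k > 0) {
      rows <- plant_base(k, "U")
      rows$age <- round(runif(k, 58, 64.9), 1)
      planted$under65 <- purrr::map(seq_len(k), function(i) {
        claim_from_subject(rows[i, ], codes,
                           sample(c(codes$evar_proc[1], codes$oar_proc[1]), 1))
      }) |> bind_rows()
    }
    k <- floor(inel$conversion * n)
    if (k > 0) {
      rows <- plant_base(k, "C")
      planted$conversion <- purrr::map(seq_len(k), function(i) {
        claim_from_subject(rows[i, ], codes, codes$evar_proc[1],
                           extra_proc = codes$oar_proc[1])
      }) |> bind_rows()
    }
    k <- floor(inel$excluded_dx * n)
    if (k > 0) {
      rows <- plant_base(k, "D")
      planted$excluded_dx <- purrr::map(seq_len(k), function(i) {
        claim_from_subject(rows[i, ], codes,
                           sample(c(codes$evar_proc[1], codes$oar_proc[1]), 1),
                           extra_dx = sample(codes$excluded_dx, 1))
      }) |> bind_rows()
    }
    k <- floor(inel$excluded_proc * n)
    if (k > 0) {
      rows <- plant_base(k, "P")
      planted$excluded_proc <- purrr::map(seq_len(k), function(i) {
        claim_from_subject(rows[i, ], codes,
                           sample(c(codes$evar_proc[1], codes$oar_proc[1]), 1),
                           extra_proc = sample(codes$excluded_proc, 1))
      }) |> bind_rows()
    }
    k <- floor(inel$short_enrollment * n)
    if (k > 0) {
      rows <- plant_base(k, "E")
      planted$short_enrollment <- purrr::map(seq_len(k), function(i) {
        claim_from_subject(rows[i, ], codes,
                           sample(c(codes$evar_proc[1], codes$oar_proc[1]), 1),
                           enroll_back_days = sample(30:300, 1))
      }) |> bind_rows()
    }
    # duplicate later claims for eligible beneficiaries (first-claim rule)
    k <- floor(inel$duplicates * n)
    if (k > 0) {
      idx <- sample.int(n, k)
      dup <- purrr::map(idx, function(i) {
        row <- cohort[i, ]
        row$treatment_date <- row$treatment_date + sample(60:400, 1)
        claim_from_subject(row, codes, proc[i])
      }) |> bind_rows()
      planted$duplicates <- dup
    }

    planted <- bind_rows(planted)
    if (nrow(planted) > 0) {
      planted$death_date <- as.Date(NA)
      planted$enrollment_end <- as.Date(NA)
      claims <- bind_rows(claims, planted)
    }

    claims <- claims |>
      mutate(claim_id = sprintf("CLM%06d", dplyr::row_number())) |>
      select("claim_id", dplyr::everything())

    list(claims = claims, cohort = cohort, ground_truth = sim$ground_truth)
  })
}
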