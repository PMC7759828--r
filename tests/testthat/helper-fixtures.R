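# Shared fixtures, all built in code.

# Fixed 50-row survival dataset with weights, used for the
# cross-implementation and linear-equivalence oracles.
small_cox_fixture <- function(n = 50, seed = 42) {
  withr::with_seed(seed, {
    x <- cbind(a = rnorm(n), b = rbinom(n, 1, 0.5))
    z <- rbinom(n, 1, 0.5)
    tm <- rexp(n, exp(0.4 * x[, 1] - 0.3 * x[, 2] - 0.3 * z))
    st <- rbinom(n, 1, 0.8)
    w <- runif(n, 0.5, 2.5)
    list(x = x, z = z, time = tm, status = st, w = w)
  })
}

# Ten hand-written claims: 5 eligible subjects once the filters run.
# B1, B2, B7 (first claim), B8, B9 survive; excluded are two under-65
# claims, one conversion, one short-enrolment, and B7's later claim.
eligibility_fixture <- function() {
  base <- function(id, admission, age = 75, proc = "PROC_EVAR",
                   dx = "DX_RUPT", enroll_back = 400) {
    admission <- as.Date(admission)
    tibble::tibble(
      beneficiary_id = id,
      admission_date = admission,
      discharge_date = admission + 6,
      treatment_date = admission + 1,
      age_at_admission = age,
      sex = "male", race = "white",
      enrollment_start = admission - enroll_back,
      enrollment_end = as.Date(NA),
      death_date = as.Date(NA),
      diagnosis_codes = dx,
      procedure_codes = proc
    )
  }
  dplyr::bind_rows(
    base("B1", "2012-03-01"),
    base("B2", "2012-04-01", proc = "PROC_OAR"),
    base("B3", "2012-05-01", age = 62),
    base("B4", "2012-06-01", age = 60, proc = "PROC_OAR"),
    base("B5", "2012-07-01", proc = "PROC_EVAR;PROC_OAR"),
    base("B6", "2012-08-01", enroll_back = 100),
    base("B7", "2012-09-01"),
    base("B7", "2013-02-01"),            # later claim, same beneficiary
    base("B8", "2013-03-01", proc = "PROC_OAR"),
    base("B9", "2013-04-01")
  )
}

# Rebuild a cohort whose per-arm counts equal the printed descriptive table
# of the study being emulated (arm sizes 3960 treated / 3866 control), so
# the descriptive engine's percentages can be checked against the printed
# values. Only count-determined columns are populated.
printed_table1_counts <- function() {
  list(
    n = c(`1` = 3960, `0` = 3866),
    male = c(3023, 2786),
    race = list(white = c(3588, 3550), black = c(249, 178),
                other = c(116, 130)),                  # rest missing
    conditions = list(
      chf = c(464, 299), arrhythmia = c(596, 438), valvular = c(199, 172),
      coronary = c(758, 603), diabetes = c(329, 256),
      hypertension = c(1250, 1078), copd = c(707, 584),
      lower_extremity_vascular = c(26, 27), renal_atherosclerosis = c(20, 27),
      vascular_intestine = c(7, 2), renal_failure = c(493, 358),
      other_renal = c(3, 1), kidney_transplant = c(4, 3),
      liver_disease = c(33, 30), cerebrovascular = c(93, 67),
      other_neurological = c(153, 114), hyperlipidemia = c(817, 687),
      cancer = c(132, 87), rheumatoid_arthritis = c(76, 39),
      prior_intact_aaa = c(511, 440)
    ),
    year = list(`2011` = c(808, 1013), `2012` = c(869, 913),
                `2013` = c(819, 785), `2014` = c(837, 701),
                `2015` = c(627, 454)),
    all_cause = c(2430, 2542),
    perioperative = c(1107, 1704)
  )
}

table1_cohort <- function() {
  cts <- printed_table1_counts()
  fill_binary <- function(n, k) c(rep(1L, k), rep(0L, n - k))
  arm <- function(z) {
    i <- if (z == 1) 1L else 2L
    n <- cts$n[[as.character(z)]]
    race_counts <- vapply(cts$race, `[`, numeric(1), i)
    race <- c(rep(names(race_counts), race_counts),
              rep(NA_character_, n - sum(race_counts)))
    year_counts <- vapply(cts$year, `[`, numeric(1), i)
    df <- tibble::tibble(
      treatment = z,
      sex = c(rep("male", cts$male[i]), rep("female", n - cts$male[i])),
      race = race,
      repair_year = as.integer(rep(names(year_counts), year_counts)),
      event_long = fill_binary(n, cts$all_cause[i]),
      event_short = fill_binary(n, cts$perioperative[i])
    )
    for (cn in names(cts$conditions)) {
      df[[cn]] <- fill_binary(n, cts$conditions[[cn]][i])
    }
    df
  }
  dplyr::bind_rows(arm(1), arm(0))
}

# Covariate matrix carrying every true log-hazard effect of the default
# generator, for correctly-specified Cox fits in diagnostics tests.
true_effect_design <- function(cohort) {
  cbind(age = cohort$age, male = as.numeric(cohort$sex == "male"),
        chf = cohort$chf, copd = cohort$copd,
        renal_failure = cohort$renal_failure, cancer = cohort$cancer)
}

pipeline_smoke_config <- function(seed = 9) {
  pipeline_config(
    sim = sim_config(n_beneficiaries = 300, seed = 4),
    epochs_ps = 20L, epochs_surv = 25L, lr_grid_ps = 0.01,
    hidden_ps = 4L, hidden_surv = c(4L), B = 2L, seed = seed
  )
}

# one shared smoke-run bundle, computed lazily
.smoke_cache <- new.env(parent = emptyenv())
smoke_bundle <- function() {
  if (is.null(.smoke_cache$bundle)) {
    .smoke_cache$bundle <- suppressMessages(run_pipeline(pipeline_smoke_config()))
  }
  .smoke_cache$bundle
}
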