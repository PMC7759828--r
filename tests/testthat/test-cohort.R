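test_that("the hand-built claims fixture yields five eligible subjects", {
  res <- apply_eligibility(eligibility_fixture())
  expect_equal(nrow(res$claims), 5L)
  expect_setequal(res$claims$beneficiary_id, c("B1", "B2", "B7", "B8", "B9"))
  log <- res$log
  get <- function(cr) log$n_excluded[log$criterion == cr]
  expect_equal(get("age under 65"), 2L)
  expect_equal(get("conversion (both repair procedures)"), 1L)
  expect_equal(get("under 12 months prior enrollment"), 1L)
  expect_equal(get("later claim of same beneficiary"), 1L)
  # B7's first claim is the one kept
  expect_equal(res$claims$admission_date[res$claims$beneficiary_id == "B7"],
               as.Date("2012-09-01"))
})

test_that("a conversion claim with both repair code sets is excluded", {
  claims <- eligibility_fixture()[5, ]
  res <- apply_eligibility(claims)
  expect_equal(nrow(res$claims), 0L)
  expect_equal(
    res$log$n_excluded[res$log$criterion ==
                         "conversion (both repair procedures)"], 1L)
})

test_that("empty claims give an empty cohort and all-zero log", {
  res <- apply_eligibility(eligibility_fixture()[0, ])
  expect_equal(nrow(res$claims), 0L)
  expect_true(all(res$log$n_excluded == 0))
  expect_true(all(res$log$n_remaining == 0))
})

test_that("eligibility filtering is idempotent and conserves counts", {
  claims <- eligibility_fixture()
  first <- apply_eligibility(claims)
  second <- apply_eligibility(first$claims)
  expect_identical(second$claims, first$claims)
  expect_true(all(second$log$n_excluded == 0))
  # conservation at every step: excluded + remaining = previous remaining
  log <- first$log
  prev <- c(nrow(claims), utils::head(log$n_remaining, -1))
  expect_equal(log$n_excluded + log$n_remaining, prev)
})

test_that("unparseable dates are rejected with their own log entry", {
  claims <- eligibility_fixture()
  claims$admission_date <- as.character(claims$admission_date)
  claims$admission_date[1] <- "not-a-date"
  res <- apply_eligibility(claims)
  expect_equal(res$log$n_excluded[res$log$criterion == "unparseable dates"],
               1L)
  expect_equal(nrow(res$claims), 4L)
})

test_that("treatment-date imputation uses the admission date", {
  claims <- eligibility_fixture()[1:2, ]
  claims$treatment_date[1] <- as.Date(NA)
  claims$admission_date[1] <- as.Date("2012-03-01")
  out <- suppressMessages(impute_treatment_date(claims))
  expect_equal(out$treatment_date[1], as.Date("2012-03-01"))
  expect_equal(out$treatment_date[2], claims$treatment_date[2])  # untouched
  expect_equal(attr(out, "imputed_fraction"), 0.5)
})

test_that("outcome derivation follows the perioperative and long-term rules", {
  mk <- function(death_offset, enrollment_end = as.Date(NA)) {
    tibble::tibble(
      beneficiary_id = "B1",
      admission_date = as.Date("2012-01-01"),
      discharge_date = as.Date("2012-01-06"),     # day 5
      treatment_date = as.Date("2012-01-01"),     # day 0
      age_at_admission = 75, sex = "male", race = "white",
      enrollment_start = as.Date("2010-01-01"),
      enrollment_end = enrollment_end,
      death_date = if (is.na(death_offset)) as.Date(NA) else
        as.Date("2012-01-01") + death_offset,
      diagnosis_codes = "DX_RUPT;DX_CHF",
      procedure_codes = "PROC_EVAR"
    )
  }
  study_end <- as.Date("2012-01-01") + 1000

  # death day 20 <= discharge + 30 = 35: event for both outcomes
  co <- derive_outcomes(mk(20), study_end)
  expect_equal(co$time_short, 20)
  expect_equal(co$event_short, 1L)
  expect_equal(co$time_long, 20)
  expect_equal(co$event_long, 1L)
  expect_equal(co$chf, 1L)          # condition flag extracted from dx codes
  expect_equal(co$treatment, 1L)

  # death day 40 > 35: short-term censored at 35, long-term event at 40
  co <- derive_outcomes(mk(40), study_end)
  expect_equal(co$time_short, 35)
  expect_equal(co$event_short, 0L)
  expect_equal(co$time_long, 40)
  expect_equal(co$event_long, 1L)

  # no death: long-term censored at the study end
  co <- derive_outcomes(mk(NA), study_end)
  expect_equal(co$time_long, 1000)
  expect_equal(co$event_long, 0L)

  # loss to follow-up before the study end wins
  co <- derive_outcomes(mk(NA, enrollment_end = as.Date("2012-01-01") + 200),
                        study_end)
  expect_equal(co$time_long, 200)

  # death before treatment is rejected with a diagnostic
  expect_warning(co <- derive_outcomes(mk(-3), study_end), "death before")
  expect_equal(nrow(co), 0L)
  expect_equal(nrow(attr(co, "rejected")), 1L)
})

test_that("claims assembled end-to-end reproduce the generating cohort", {
  cfg <- sim_config(n_beneficiaries = 300, seed = 21,
                    missingness_spec = list(treatment_date = 0,
                                            covariates = 0))
  sim <- simulate_claims(cfg)
  res <- apply_eligibility(sim$claims)
  cohort <- derive_outcomes(suppressMessages(impute_treatment_date(res$claims)))
  expect_equal(nrow(cohort), 300L)
  merged <- dplyr::inner_join(cohort, sim$cohort, by = "subject_id",
                              suffix = c("", ".gen"))
  expect_equal(merged$treatment, merged$treatment.gen)
  expect_equal(merged$chf, merged$chf.gen)
  expect_equal(merged$event_short, merged$event_short.gen)
  # death dates are rounded to days in claims; times agree to that precision
  expect_true(all(abs(merged$time_long - merged$time_long.gen) <= 0.5 + 1e-9))
  expect_true(all(cohort$time_short <= cohort$time_long))
  expect_true(all(cohort$event_long[cohort$event_short == 1] == 1))
})

test_that("drop_incomplete removes exactly the planted missing rows", {
  co <- simulate_cohort(sim_config(n_beneficiaries = 100, seed = 9,
                                   missingness_spec = list(covariates = 0)))$cohort
  co$race[c(2, 50, 99)] <- NA
  out <- suppressMessages(drop_incomplete(co))
  expect_equal(attr(out, "n_dropped"), 3L)
  expect_equal(nrow(out), 97L)
  # identity when nothing is missing
  out2 <- suppressMessages(drop_incomplete(out))
  expect_equal(nrow(out2), 97L)
  # everything missing warns and empties
  co$race <- NA
  expect_warning(out3 <- drop_incomplete(co), "all rows")
  expect_equal(nrow(out3), 0L)
})

test_that("the exclusion log round-trips through its JSON serialisation", {
  res <- apply_eligibility(eligibility_fixture())
  path <- withr::local_tempfile(fileext = ".json")
  write_exclusion_log(res$log, path)
  back <- jsonlite::fromJSON(path)
  expect_equal(back$criterion, res$log$criterion)
  expect_equal(back$n_remaining, res$log$n_remaining)
})
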