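# Claims-to-cohort assembly: eligibility filtering, treatment-date
# imputation, outcome derivation, and missing-covariate handling.

split_codes <- function(x) {
  if (length(x) == 0) return(list())
  strsplit(ifelse(is.na(x), "", as.character(x)), ";", fixed = TRUE)
}

has_any_code <- function(code_col, codes) {
  if (length(codes) == 0) return(rep(FALSE, length(code_col)))
  map_lgl(split_codes(code_col), function(v) any(v %in% codes))
}

#' Apply the emulated-trial eligibility filters to claims
#'
#' Identifies index claims (a rupture diagnosis plus at least one repair
#' procedure code, admitted within the enrolment window) and then applies the
#' exclusion criteria in protocol order: age under 65 at the index admission;
#' both repair code sets in the same index hospitalization (conversion);
#' concurrent excluded diagnosis codes; concurrent excluded procedure codes;
#' fewer than 12 months of enrolment before the index admission (calendar
#' arithmetic, `enrollment_start <= admission - 365`); and, for
#' beneficiaries with several eligible claims, all but the first (ordered by
#' admission date, ties by file order). Concurrent codes are checked on the
#' index claim only. Records whose dates fail to parse are rejected up front
#' with their own log entry.
#'
#' @param claims Claims tibble (see [simulate_claims()] for the column
#'   dictionary). Date columns may be `Date` or ISO-8601 strings.
#' @param codes Code-list configuration, see [default_code_lists()].
#' @param window Length-2 enrolment window (admission dates retained),
#'   default 2011-01-01 to 2015-09-30.
#' @return A list with `claims` (the eligible claims, one per subject) and
#'   `log`, a tibble of class `exclusion_log` with one ordered row per
#'   criterion: `criterion`, `n_excluded`, `n_remaining`.
#' @export
apply_eligibility <- function(claims, codes = default_code_lists(),
                              window = as.Date(c("2011-01-01",
                                                 "2015-09-30"))) {
  stopifnot(length(codes$rupture_dx) > 0, length(codes$evar_proc) > 0,
            length(codes$oar_proc) > 0)
  window <- as.Date(window)

  steps <- list()
  n0 <- nrow(claims)
  log_step <- function(label, keep, df) {
    steps[[length(steps) + 1L]] <<- tibble(
      criterion = label,
      n_excluded = sum(!keep),
      n_remaining = sum(keep)
    )
    df[keep, , drop = FALSE]
  }

  if (n0 == 0) {
    claims$.parsed <- NULL
    empty_log <- tibble(
      criterion = c("unparseable dates", "no index rupture repair in window",
                    "age under 65", "conversion (both repair procedures)",
                    "concurrent excluded diagnosis",
                    "concurrent excluded procedure",
                    "under 12 months prior enrollment",
                    "later claim of same beneficiary"),
      n_excluded = 0L, n_remaining = 0L
    )
    class(empty_log) <- c("exclusion_log", class(empty_log))
    return(list(claims = claims, log = empty_log))
  }

  # -- date parsing ----------------------------------------------------------
  date_cols <- c("admission_date", "discharge_date", "treatment_date",
                 "enrollment_start", "enrollment_end", "death_date")
  parsed <- claims
  bad <- rep(FALSE, n0)
  for (dc in intersect(date_cols, names(parsed))) {
    if (!inherits(parsed[[dc]], "Date")) {
      raw <- parsed[[dc]]
      conv <- suppressWarnings(as.Date(raw, format = "%Y-%m-%d"))
      bad <- bad | (!is.na(raw) & nzchar(trimws(as.character(raw))) &
                      is.na(conv))
      parsed[[dc]] <- conv
    }
  }
  # required dates must be present and parsed
  bad <- bad | is.na(parsed$admission_date) | is.na(parsed$discharge_date) |
    is.na(parsed$enrollment_start)
  out <- log_step("unparseable dates", !bad, parsed)

  # -- identification --------------------------------------------------------
  has_rupt <- has_any_code(out$diagnosis_codes, codes$rupture_dx)
  has_evar <- has_any_code(out$procedure_codes, codes$evar_proc)
  has_oar <- has_any_code(out$procedure_codes, codes$oar_proc)
  in_window <- out$admission_date >= window[1] & out$admission_date <= window[2]
  keep <- has_rupt & (has_evar | has_oar) & in_window
  out <- log_step("no index rupture repair in window", keep, out)

  # -- exclusions, in protocol order ----------------------------------------
  out <- log_step("age under 65", out$age_at_admission >= 65, out)

  has_evar <- has_any_code(out$procedure_codes, codes$evar_proc)
  has_oar <- has_any_code(out$procedure_codes, codes$oar_proc)
  out <- log_step("conversion (both repair procedures)", !(has_evar & has_oar),
                  out)

  out <- log_step("concurrent excluded diagnosis",
                  !has_any_code(out$diagnosis_codes, codes$excluded_dx), out)
  out <- log_step("concurrent excluded procedure",
                  !has_any_code(out$procedure_codes, codes$excluded_proc), out)
  out <- log_step("under 12 months prior enrollment",
                  out$enrollment_start <= out$admission_date - 365, out)

  # first eligible claim per beneficiary: admission order, ties by file order
  ord <- order(out$admission_date)        # stable sort keeps file order
  first <- !duplicated(out$beneficiary_id[ord])
  keep <- logical(nrow(out))
  keep[ord] <- first
  out <- log_step("later claim of same beneficiary", keep, out)

  log <- bind_rows(steps)
  class(log) <- c("exclusion_log", class(log))
  list(claims = out, log = log)
}

#' Impute missing treatment dates from the admission date
#'
#' Rupture repair is emergent, so the admission date approximates the
#' treatment date for claims where the latter is missing. The imputed
#' fraction is attached as attribute `imputed_fraction` and reported.
#'
#' @param claims Eligible-claims tibble.
#' @return The claims with `treatment_date` completed.
#' @export
impute_treatment_date <- function(claims) {
  miss <- is.na(claims$treatment_date)
  claims$treatment_date[miss] <- claims$admission_date[miss]
  frac <- if (nrow(claims) > 0) mean(miss) else 0
  inform(sprintf("imputed treatment date for %d of %d claims (%.2f%%)",
                 sum(miss), nrow(claims), 100 * frac))
  attr(claims, "imputed_fraction") <- frac
  claims
}

#' Derive the analysis cohort from eligible claims
#'
#' Classifies each subject into a treatment arm from the repair procedure
#' code, extracts baseline covariates (age, sex, race, repair year, and the
#' 20 condition flags from the diagnosis codes), and derives both survival
#' outcomes with the treatment date as time origin:
#' \itemize{
#'   \item short-term (perioperative): event if death occurs on or before
#'     `discharge + 30` days, time `death - treatment`; otherwise censored at
#'     `discharge + 30 - treatment`;
#'   \item long-term (all-cause): event at death if it occurs before loss to
#'     follow-up (`enrollment_end`) and the study end; otherwise censored at
#'     the earlier of the two.
#' }
#' Rows whose death date precedes the treatment date are rejected with a
#' diagnostic attribute `rejected`.
#'
#' @param claims Eligible claims with complete `treatment_date`.
#' @param study_end Administrative end of follow-up (default 2019-06-30).
#' @param codes Code-list configuration (used for arm and condition flags).
#' @return Cohort tibble: `subject_id`, `treatment` (1 = endovascular),
#'   covariates, `time_short`/`event_short`, `time_long`/`event_long`,
#'   `ipt_weight` (1), `treatment_date`.
#' @export
derive_outcomes <- function(claims, study_end = as.Date("2019-06-30"),
                            codes = default_code_lists()) {
  study_end <- as.Date(study_end)
  if (any(is.na(claims$treatment_date))) {
    abort("treatment_date must be complete; run impute_treatment_date() first.")
  }
  if (nrow(claims) == 0) {
    return(tibble())
  }

  bad <- !is.na(claims$death_date) & claims$death_date < claims$treatment_date
  rejected <- claims[bad, , drop = FALSE]
  if (nrow(rejected) > 0) {
    warn(sprintf("rejected %d record(s) with death before treatment",
                 nrow(rejected)))
  }
  claims <- claims[!bad, , drop = FALSE]

  has_evar <- has_any_code(claims$procedure_codes, codes$evar_proc)

  death_off <- as.numeric(claims$death_date - claims$treatment_date)
  short_cens <- as.numeric(claims$discharge_date + 30 - claims$treatment_date)
  short_event <- !is.na(death_off) & death_off <= short_cens
  long_cens <- pmin(
    ifelse(is.na(claims$enrollment_end), Inf,
           as.numeric(claims$enrollment_end - claims$treatment_date)),
    as.numeric(study_end - claims$treatment_date)
  )
  long_event <- !is.na(death_off) & death_off <= long_cens

  cohort <- tibble(
    subject_id = claims$beneficiary_id,
    treatment = as.integer(has_evar),
    age = claims$age_at_admission,
    sex = claims$sex,
    race = claims$race,
    repair_year = as.integer(format(claims$treatment_date, "%Y")),
    treatment_date = claims$treatment_date
  )
  cond_codes <- codes$conditions
  for (cn in condition_names()) {
    cohort[[cn]] <- as.integer(has_any_code(claims$diagnosis_codes,
                                            cond_codes[[cn]]))
    # a wholly missing diagnosis field yields 0, not NA, by claims convention
  }
  # a same-day death would give time 0; count it as half a day so survival
  # times are strictly positive and the curve's S(0) = 1 stays meaningful
  death_off <- pmax(death_off, 0.5)
  cohort$time_short <- ifelse(short_event, death_off, short_cens)
  cohort$event_short <- as.integer(short_event)
  cohort$time_long <- ifelse(long_event, death_off, long_cens)
  cohort$event_long <- as.integer(long_event)
  cohort$ipt_weight <- 1

  attr(cohort, "rejected") <- rejected
  cohort
}

#' Drop cohort rows with missing covariates
#'
#' Complete-case restriction ahead of modelling; the removed count is
#' reported and attached as attribute `n_dropped`.
#'
#' @param cohort Cohort tibble.
#' @param covariates Covariate columns to check (default: age, sex, race,
#'   repair year and the 20 condition flags).
#' @return The complete-case cohort.
#' @export
drop_incomplete <- function(cohort,
                            covariates = c("age", "sex", "race",
                                           "repair_year", condition_names())) {
  covariates <- intersect(covariates, names(cohort))
  ok <- complete.cases(cohort[, covariates, drop = FALSE])
  n_drop <- sum(!ok)
  if (n_drop == nrow(cohort) && nrow(cohort) > 0) {
    warn("all rows have missing covariates; returning empty cohort")
  } else {
    inform(sprintf("dropped %d record(s) with missing covariates", n_drop))
  }
  out <- cohort[ok, , drop = FALSE]
  attr(out, "n_dropped") <- n_drop
  out
}

#' Write the exclusion log as structured JSON
#'
#' Serialises the per-criterion flowchart (criterion, excluded, remaining)
#' so downstream tools can render the cohort-definition diagram.
#'
#' @param log An `exclusion_log` from [apply_eligibility()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_exclusion_log <- function(log, path) {
  writeLines(jsonlite::toJSON(as.data.frame(log), pretty = TRUE), path)
  invisible(path)
}
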