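# Arm-by-arm descriptive table with unadjusted outcome incidences.

#' Descriptive characteristics table by treatment arm
#'
#' Summarises baseline covariates per arm the way claims-cohort papers print
#' them: `count (percentage)` per level for categorical covariates (the
#' percentage denominator is the arm's non-missing count for that covariate)
#' and `mean (sd)` for continuous covariates, with two-sample t-test
#' (continuous) and chi-squared test (categorical, full contingency table,
#' no continuity correction) p-values. Unadjusted incidence counts and
#' percentages per arm are appended for both survival outcomes when the
#' event columns are present.
#'
#' @param cohort Cohort tibble with a binary `treatment` column.
#' @param continuous,categorical,binary Covariate column names; defaults
#'   match the cohort layout produced by this package.
#' @return A tibble of class `descriptive_table`: one row per
#'   (variable, level) with per-arm `n`/`pct` or `mean`/`sd` columns
#'   (`_1` = treated arm, `_0` = control), the test used and its p-value.
#'   Zero-variance continuous covariates get an `NA` p-value rather than an
#'   error.
#' @export
descriptive_table <- function(cohort,
                              continuous = "age",
                              categorical = c("sex", "race", "repair_year"),
                              binary = intersect(condition_names(),
                                                 names(cohort))) {
  if (!"treatment" %in% names(cohort)) abort("cohort must have `treatment`.")
  z <- cohort$treatment
  if (length(unique(z)) < 2 || min(table(z)) < 2) {
    abort("descriptive_table needs at least 2 subjects in each arm.")
  }

  rows <- list()

  for (v in intersect(continuous, names(cohort))) {
    x1 <- cohort[[v]][z == 1]
    x0 <- cohort[[v]][z == 0]
    p <- if (sd(x1, na.rm = TRUE) == 0 && sd(x0, na.rm = TRUE) == 0) {
      NA_real_
    } else {
      tryCatch(t.test(x1, x0)$p.value, error = function(e) NA_real_)
    }
    rows[[length(rows) + 1L]] <- tibble(
      variable = v, level = NA_character_, type = "continuous",
      n_1 = sum(!is.na(x1)), n_0 = sum(!is.na(x0)),
      mean_1 = mean(x1, na.rm = TRUE), sd_1 = sd(x1, na.rm = TRUE),
      mean_0 = mean(x0, na.rm = TRUE), sd_0 = sd(x0, na.rm = TRUE),
      pct_1 = NA_real_, pct_0 = NA_real_,
      test = "t", p_value = p
    )
  }

  cat_rows <- function(v, x, type) {
    x1 <- x[z == 1]
    x0 <- x[z == 0]
    tab <- table(factor(x), z)
    p <- if (nrow(tab) < 2) NA_real_ else {
      tryCatch(
        suppressWarnings(chisq.test(tab, correct = FALSE)$p.value),
        error = function(e) NA_real_
      )
    }
    levs <- rownames(tab)
    den1 <- sum(!is.na(x1))
    den0 <- sum(!is.na(x0))
    purrr::map(seq_along(levs), function(k) {
      n1 <- sum(x1 == levs[k], na.rm = TRUE)
      n0 <- sum(x0 == levs[k], na.rm = TRUE)
      tibble(
        variable = v, level = levs[k], type = type,
        n_1 = n1, n_0 = n0,
        mean_1 = NA_real_, sd_1 = NA_real_, mean_0 = NA_real_,
        sd_0 = NA_real_,
        pct_1 = 100 * n1 / den1, pct_0 = 100 * n0 / den0,
        # the test is for the whole covariate; attach it to each level
        test = "chisq", p_value = p
      )
    }) |> bind_rows()
  }

  for (v in intersect(categorical, names(cohort))) {
    rows[[length(rows) + 1L]] <- cat_rows(v, cohort[[v]], "categorical")
  }
  for (v in intersect(binary, names(cohort))) {
    r <- cat_rows(v, cohort[[v]], "binary")
    # report the presence level only, as a comorbidity table does
    if (any(r$level == "1")) r <- r[r$level == "1", , drop = FALSE]
    rows[[length(rows) + 1L]] <- r
  }

  # unadjusted outcome incidences
  for (oc in c("long", "short")) {
    ev <- paste0("event_", oc)
    if (ev %in% names(cohort)) {
      n1 <- sum(cohort[[ev]][z == 1] == 1, na.rm = TRUE)
      n0 <- sum(cohort[[ev]][z == 0] == 1, na.rm = TRUE)
      tab <- table(factor(cohort[[ev]], levels = 0:1), z)
      p <- tryCatch(
        suppressWarnings(chisq.test(tab, correct = FALSE)$p.value),
        error = function(e) NA_real_
      )
      rows[[length(rows) + 1L]] <- tibble(
        variable = if (oc == "long") "all_cause_mortality" else
          "perioperative_mortality",
        level = "1", type = "outcome",
        n_1 = n1, n_0 = n0,
        mean_1 = NA_real_, sd_1 = NA_real_, mean_0 = NA_real_, sd_0 = NA_real_,
        pct_1 = 100 * n1 / sum(z == 1), pct_0 = 100 * n0 / sum(z == 0),
        test = "chisq", p_value = p
      )
    }
  }

  out <- bind_rows(rows)
  class(out) <- c("descriptive_table", class(out))
  out
}
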