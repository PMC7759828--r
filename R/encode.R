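# Covariate encoding: standardized continuous columns, one-hot categoricals
# with a reference level, binary flags passed through.

#' Encode cohort covariates into a numeric design matrix
#'
#' Continuous covariates are standardized to mean 0 and (population) sd 1;
#' categorical covariates are one-hot encoded against a reference level (the
#' most frequent level in the training data); binary condition flags pass
#' through as 0/1. Zero-variance columns are flagged degenerate (and left as
#' zeros rather than producing NaN). When `design` is supplied, its stored
#' standardization parameters and level sets are applied to `cohort`
#' (transform mode); an unseen category is an error.
#'
#' @param cohort Cohort tibble with no missing covariates (see
#'   [drop_incomplete()]).
#' @param continuous,categorical,binary Covariate column names.
#' @param design Optional fitted `design_matrix` whose encoding to re-apply.
#' @return An object of class `design_matrix`: list with the numeric matrix
#'   `x`, a `col_map` tibble (encoded column, source covariate, level, type,
#'   degeneracy flag), `center`/`scale` for continuous columns, and the
#'   categorical `levels` (reference first).
#' @export
encode_covariates <- function(cohort,
                              continuous = "age",
                              categorical = c("sex", "race", "repair_year"),
                              binary = intersect(condition_names(),
                                                 names(cohort)),
                              design = NULL) {
  continuous <- intersect(continuous, names(cohort))
  categorical <- intersect(categorical, names(cohort))
  binary <- intersect(binary, names(cohort))
  covs <- c(continuous, categorical, binary)
  if (any(!complete.cases(cohort[, covs, drop = FALSE]))) {
    abort("cohort has missing covariates; run drop_incomplete() first.")
  }

  if (is.null(design)) {
    center <- map_dbl(cohort[continuous], mean)
    scale <- map_dbl(cohort[continuous], sd_pop)
    levels <- lapply(cohort[categorical], function(x) {
      tab <- sort(table(x), decreasing = TRUE)
      names(tab)                       # reference = most frequent, first
    })
  } else {
    stopifnot(inherits(design, "design_matrix"))
    continuous <- design$continuous
    categorical <- design$categorical
    binary <- design$binary
    center <- design$center
    scale <- design$scale
    levels <- design$levels
    for (v in categorical) {
      unseen <- setdiff(unique(as.character(cohort[[v]])), levels[[v]])
      if (length(unseen) > 0) {
        abort(sprintf("unseen level(s) in `%s`: %s", v,
                      paste(unseen, collapse = ", ")))
      }
    }
  }

  cols <- list()
  col_map <- list()
  add_col <- function(name, values, source, level, type, degenerate) {
    cols[[name]] <<- values
    col_map[[length(col_map) + 1L]] <<- tibble(
      column = name, source = source, level = level, type = type,
      degenerate = degenerate
    )
  }

  for (v in continuous) {
    s <- scale[[v]]
    degen <- !is.finite(s) || s == 0
    vals <- if (degen) rep(0, nrow(cohort)) else (cohort[[v]] - center[[v]]) / s
    add_col(v, vals, v, NA_character_, "continuous", degen)
  }
  for (v in categorical) {
    levs <- levels[[v]]
    degen_var <- length(levs) < 2
    for (lv in levs[-1]) {
      vals <- as.numeric(as.character(cohort[[v]]) == lv)
      add_col(paste0(v, "_", lv), vals, v, lv, "categorical",
              degen_var || length(unique(vals)) < 2)
    }
    if (degen_var) {
      # single-level categorical: no contrast column, but record the fact
      col_map[[length(col_map) + 1L]] <- tibble(
        column = NA_character_, source = v, level = levs[1] %g0% NA_character_,
        type = "categorical", degenerate = TRUE
      )
    }
  }
  for (v in binary) {
    vals <- as.numeric(cohort[[v]])
    add_col(v, vals, v, NA_character_, "binary", length(unique(vals)) < 2)
  }

  x <- do.call(cbind, cols)
  rownames(x) <- NULL
  structure(
    list(
      x = x,
      col_map = bind_rows(col_map),
      center = center, scale = scale, levels = levels,
      continuous = continuous, categorical = categorical, binary = binary
    ),
    class = "design_matrix"
  )
}

#' @export
print.design_matrix <- function(x, ...) {
  cat("<design_matrix> ", nrow(x$x), " x ", ncol(x$x), " (",
      sum(x$col_map$degenerate), " degenerate column(s))\n", sep = "")
  invisible(x)
}

design_x <- function(design) {
  if (inherits(design, "design_matrix")) design$x else as.matrix(design)
}

# Non-degenerate encoded columns only (drops constants, e.g. a rare
# condition absent from a small cohort) — what a regression fit can use.
design_x_nondegenerate <- function(design) {
  if (!inherits(design, "design_matrix")) return(as.matrix(design))
  keep <- design$col_map$column[!design$col_map$degenerate &
                                  !is.na(design$col_map$column)]
  design$x[, keep, drop = FALSE]
}
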