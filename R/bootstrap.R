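# 0.632 subsample bootstrap: repeated propensity + survival refits on
# floor(0.632 n) subjects drawn without replacement, with quantile summaries
# of the accumulated weights and pointwise survival-curve bands.

#' Draw a 0.632 subsample index set
#'
#' `floor(0.632 * n)` distinct indices drawn uniformly without replacement.
#' Sampling without replacement at this fraction matches, in expectation,
#' the classical n-out-of-n with-replacement bootstrap while avoiding ties.
#'
#' @param n Cohort size (>= 2).
#' @param seed Integer seed (deterministic output).
#' @return Integer vector of `floor(0.632 * n)` distinct indices.
#' @export
subsample_632 <- function(n, seed = NULL) {
  if (n < 2) abort("`n` must be at least 2.")
  m <- floor(0.632 * n)
  with_seed(seed, sample.int(n, m))
}

# Hyperparameters for one bootstrap pipeline refit; defaults are reused from
# the full-data fit rather than re-tuned per replicate.
bootstrap_config <- function(outcome = c("long", "short"),
                             hidden_ps = 16L,
                             hidden_surv = c(16L, 8L),
                             lr_ps = 0.008,
                             lr_surv = 0.016,
                             epochs_ps = 60L,
                             epochs_surv = 80L,
                             clip = 0.01,
                             refit_propensity = TRUE,
                             weight_denominator = FALSE) {
  outcome <- match.arg(outcome)
  list(outcome = outcome, hidden_ps = hidden_ps, hidden_surv = hidden_surv,
       lr_ps = lr_ps, lr_surv = lr_surv, epochs_ps = epochs_ps,
       epochs_surv = epochs_surv, clip = clip,
       refit_propensity = refit_propensity,
       weight_denominator = weight_denominator)
}

# One pipeline pass on a cohort subset: encode, fit propensity (or reuse
# supplied weights), IPT-weight, fit the survival network, accumulate
# weights, evaluate curves on the common grid.
fit_pipeline_once <- function(cohort, config, seed, grid,
                              fixed_weights = NULL) {
  if (length(unique(cohort$treatment)) < 2) {
    abort("subsample contains a single treatment arm")
  }
  tcol <- paste0("time_", config$outcome)
  ecol <- paste0("event_", config$outcome)
  if (sum(cohort[[ecol]]) < 2) abort("subsample has fewer than 2 events")

  design <- encode_covariates(cohort)
  if (config$refit_propensity) {
    ps <- fit_propensity(design, cohort$treatment, hidden = config$hidden_ps,
                         lr_grid = config$lr_ps, epochs = config$epochs_ps,
                         seed = seed)
    scores <- predict_propensity(ps, design)
    w <- compute_ipt_weights(scores, cohort$treatment, clip = config$clip)
  } else {
    w <- fixed_weights
  }
  net <- fit_survival_network(
    design, cohort$treatment, cohort[[tcol]], cohort[[ecol]], weights = w,
    hidden = config$hidden_surv, lr_grid = config$lr_surv,
    epochs = config$epochs_surv, seed = seed,
    weight_denominator = config$weight_denominator
  )
  base <- breslow_baseline(net, design, cohort$treatment, cohort[[tcol]],
                           cohort[[ecol]], weights = w)
  curves <- marginal_survival_curves(net, base, design)
  # evaluate each arm's step curve on the common grid
  curve_on_grid <- function(arm) {
    cc <- curves[curves$arm == arm, ]
    stats::approx(cc$time, cc$surv, xout = grid, method = "constant",
                  rule = 2, f = 0, ties = "ordered")$y
  }
  list(
    accumulated = accumulate_weights(net),
    surv0 = curve_on_grid(0),
    surv1 = curve_on_grid(1),
    weights = w,
    loss = net$final_loss
  )
}

#' Run the 0.632 subsample bootstrap over the analysis pipeline
#'
#' For each replicate: draw a [subsample_632()] index set, refit the
#' propensity network on the subsample, recompute IPT weights, refit the
#' survival network, extract the layer-accumulated weights, and evaluate
#' both arms' marginal survival curves on a common grid (the distinct event
#' times of the full cohort). Per-replicate seeds derive deterministically
#' from `base_seed`. Replicates that fail (e.g. a single-arm subsample) are
#' logged and skipped; more than 10% failures aborts with diagnostics.
#'
#' @param cohort Analysis cohort (complete covariates, both outcome column
#'   pairs or at least the configured one).
#' @param B Number of replicates.
#' @param config Pipeline hyperparameters from [bootstrap_config()].
#' @param base_seed Integer seed driving all replicate seeds.
#' @return List of class `bootstrap_replicates`: `replicates` (list with
#'   per-replicate index set, accumulated weight vector and curves),
#'   `grid`, `n_failed`, `failures` (messages), `B`, `config`.
#' @export
run_bootstrap <- function(cohort, B = 200L, config = bootstrap_config(),
                          base_seed = 1L) {
  n <- nrow(cohort)
  tcol <- paste0("time_", config$outcome)
  ecol <- paste0("event_", config$outcome)
  grid <- sort(unique(cohort[[tcol]][cohort[[ecol]] == 1]))
  seeds <- derive_seeds(base_seed, 2L * B)
  sub_seeds <- seeds[seq_len(B)]
  fit_seeds <- seeds[B + seq_len(B)]

  replicates <- vector("list", B)
  failures <- character()
  for (b in seq_len(B)) {
    idx <- subsample_632(n, sub_seeds[b])
    rep_fit <- tryCatch(
      fit_pipeline_once(cohort[idx, , drop = FALSE], config, fit_seeds[b],
                        grid),
      error = function(e) conditionMessage(e)
    )
    if (is.character(rep_fit)) {
      failures <- c(failures, sprintf("replicate %d: %s", b, rep_fit))
      replicates[b] <- list(NULL)
    } else {
      replicates[[b]] <- c(list(replicate = b, indices = idx), rep_fit)
    }
  }
  n_failed <- length(failures)
  if (n_failed > 0.1 * B) {
    abort(paste0(
      sprintf("%d of %d bootstrap replicates failed:\n", n_failed, B),
      paste(head(failures, 5L), collapse = "\n")
    ))
  }
  structure(
    list(replicates = compact(replicates), grid = grid, n_failed = n_failed,
         failures = failures, B = B, config = config),
    class = "bootstrap_replicates"
  )
}

#' @export
print.bootstrap_replicates <- function(x, ...) {
  cat("<bootstrap_replicates>", length(x$replicates), "successful of", x$B,
      "replicates (", x$n_failed, "failed ) on a grid of",
      length(x$grid), "times\n")
  invisible(x)
}

#' Summarise bootstrap replicates
#'
#' Empirical quantiles across replicates: median and 25%/75% quantiles of
#' each input's accumulated weight (the forest-plot numbers), and pointwise
#' 5%/95% quantiles of the survival curves per arm (a 90% band), plus the
#' replicate median curve. Quantiles use linear interpolation between order
#' statistics (type 7). The summary is invariant to replicate order.
#'
#' @param replicates A `bootstrap_replicates` object (>= 2 successes).
#' @return Object of class `bootstrap_summary`: `weights` tibble (feature,
#'   q25, median, q75), `bands` tibble (arm, time, lower, median, upper),
#'   `B_success`.
#' @export
summarize_bootstrap <- function(replicates) {
  stopifnot(inherits(replicates, "bootstrap_replicates"))
  reps <- replicates$replicates
  if (length(reps) < 2) abort("need at least 2 successful replicates.")

  wmat <- do.call(rbind, lapply(reps, `[[`, "accumulated"))
  weights <- tibble(
    feature = colnames(wmat),
    q25 = unname(apply(wmat, 2L, quantile, probs = 0.25, type = 7)),
    median = unname(apply(wmat, 2L, median)),
    q75 = unname(apply(wmat, 2L, quantile, probs = 0.75, type = 7))
  )

  band_for <- function(key, arm) {
    smat <- do.call(rbind, lapply(reps, `[[`, key))
    tibble(
      arm = arm,
      time = replicates$grid,
      lower = apply(smat, 2L, quantile, probs = 0.05, type = 7),
      median = apply(smat, 2L, median),
      upper = apply(smat, 2L, quantile, probs = 0.95, type = 7)
    )
  }
  bands <- bind_rows(band_for("surv0", 0L), band_for("surv1", 1L))

  structure(
    list(weights = weights, bands = bands, B_success = length(reps),
         n_failed = replicates$n_failed),
    class = "bootstrap_summary"
  )
}

#' @export
print.bootstrap_summary <- function(x, ...) {
  cat("<bootstrap_summary> from", x$B_success, "replicates\n")
  print(x$weights)
  invisible(x)
}
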