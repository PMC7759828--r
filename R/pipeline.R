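# End-to-end orchestration: simulate -> assemble -> propensity -> survival
# -> Cox comparator -> bootstrap -> report, with a reproducibility manifest.

#' Build a pipeline configuration
#'
#' One flat configuration driving every stage of [run_pipeline()]. Defaults
#' follow the emulated-trial protocol: enrolment window 2011-01-01 to
#' 2015-09-30, administrative study end 2019-06-30, both outcomes analysed.
#'
#' @param sim A [sim_config()] for the synthetic claims stage (or `NULL`
#'   when `claims` are supplied to [run_pipeline()] directly).
#' @param codes Code-list configuration ([default_code_lists()]).
#' @param study_end Administrative end of follow-up.
#' @param window Enrolment window for index admissions.
#' @param outcomes Outcomes to analyse, subset of `c("long", "short")`.
#' @param hidden_ps,lr_grid_ps,epochs_ps Propensity-network hyperparameters.
#' @param hidden_surv,lr_grid_surv,epochs_surv Survival-network
#'   hyperparameters.
#' @param clip IPT weight clipping threshold.
#' @param B Bootstrap replicates (0 skips the bootstrap).
#' @param bootstrap_outcome Outcome the bootstrap summarises.
#' @param seed Master seed for every stochastic stage.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            codes = default_code_lists(),
                            study_end = as.Date("2019-06-30"),
                            window = as.Date(c("2011-01-01", "2015-09-30")),
                            outcomes = c("long", "short"),
                            hidden_ps = 16L,
                            lr_grid_ps = exp(seq(log(0.001), log(0.05),
                                                 length.out = 5)),
                            epochs_ps = 100L,
                            hidden_surv = c(16L, 8L),
                            lr_grid_surv = 0.016,
                            epochs_surv = 100L,
                            clip = 0.01,
                            B = 50L,
                            bootstrap_outcome = "long",
                            seed = 1L) {
  study_end <- as.Date(study_end)
  window <- as.Date(window)
  if (window[1] >= window[2] || window[2] > study_end) {
    abort("dates must satisfy window start < window end <= study_end.")
  }
  outcomes <- match.arg(outcomes, c("long", "short"), several.ok = TRUE)
  structure(
    list(sim = sim, codes = codes, study_end = study_end, window = window,
         outcomes = outcomes, hidden_ps = hidden_ps,
         lr_grid_ps = lr_grid_ps, epochs_ps = epochs_ps,
         hidden_surv = hidden_surv, lr_grid_surv = lr_grid_surv,
         epochs_surv = epochs_surv, clip = clip, B = as.integer(B),
         bootstrap_outcome = bootstrap_outcome, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

config_hash <- function(config) {
  if (requireNamespace("rlang", quietly = TRUE) &&
      "hash" %in% getNamespaceExports("rlang")) {
    rlang::hash(config)
  } else {
    # stable fallback: sum over the serialized bytes
    raw <- serialize(config, NULL, version = 3L)
    sprintf("%08x-%d", sum(as.integer(raw)) %% 0xFFFFFFF, length(raw))
  }
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", name,
                  conditionMessage(e)))
  })
}

#' Run the full emulation pipeline
#'
#' Executes simulate (unless `claims` are supplied), assemble (eligibility
#' filters, treatment-date imputation, outcome derivation, complete-case
#' restriction, descriptive table), propensity (encode, fit, IPT weights,
#' balance), survival (network, Breslow baseline, marginal curves, expected
#' survival) and Cox comparator (fit + proportionality test) per outcome,
#' and the 0.632 bootstrap for `bootstrap_outcome`. Every stage error is
#' re-raised with the stage name. A manifest records the configuration
#' hash, seed and package version; rerunning the same configuration
#' reproduces all numeric outputs.
#'
#' @param config A [pipeline_config()].
#' @param claims Optional claims tibble to analyse instead of simulating.
#' @return List of class `emulation_bundle` with elements `claims`,
#'   `exclusion_log`, `cohort`, `descriptives`, `propensity` (model, scores,
#'   weights, balance), per-outcome `survival` (network, baseline, curves,
#'   expected survival) and `cox` (fit, PH test), `bootstrap` (replicates +
#'   summary, or NULL), `ground_truth` (when simulated) and `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), claims = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  ground_truth <- NULL

  if (is.null(claims)) {
    simd <- stage("simulate", {
      if (is.null(config$sim)) abort("no sim config and no claims supplied")
      simulate_claims(config$sim, config$codes)
    })
    claims <- simd$claims
    ground_truth <- simd$ground_truth
  }

  assembled <- stage("assemble", {
    elig <- apply_eligibility(claims, config$codes, config$window)
    imputed <- impute_treatment_date(elig$claims)
    cohort <- derive_outcomes(imputed, config$study_end, config$codes)
    cohort <- drop_incomplete(cohort)
    list(cohort = cohort, log = elig$log,
         imputed_fraction = attr(imputed, "imputed_fraction"))
  })
  cohort <- assembled$cohort

  descriptives <- stage("describe", descriptive_table(cohort))

  prop <- stage("propensity", {
    design <- encode_covariates(cohort)
    model <- fit_propensity(design, cohort$treatment,
                            hidden = config$hidden_ps,
                            lr_grid = config$lr_grid_ps,
                            epochs = config$epochs_ps, seed = config$seed)
    scores <- predict_propensity(model, design)
    weights <- compute_ipt_weights(scores, cohort$treatment,
                                   clip = config$clip)
    balance <- balance_diagnostics(design, cohort$treatment, weights)
    list(design = design, model = model, scores = scores, weights = weights,
         balance = balance)
  })

  survival <- list()
  cox <- list()
  for (oc in config$outcomes) {
    tcol <- paste0("time_", oc)
    ecol <- paste0("event_", oc)
    survival[[oc]] <- stage(paste0("survival_", oc), {
      net <- fit_survival_network(
        prop$design, cohort$treatment, cohort[[tcol]], cohort[[ecol]],
        weights = prop$weights, hidden = config$hidden_surv,
        lr_grid = config$lr_grid_surv, epochs = config$epochs_surv,
        seed = config$seed
      )
      base <- breslow_baseline(net, prop$design, cohort$treatment,
                               cohort[[tcol]], cohort[[ecol]],
                               weights = prop$weights)
      curves <- marginal_survival_curves(net, base, prop$design)
      exp_surv <- c(
        arm0 = expected_survival(curves[curves$arm == 0, ]),
        arm1 = expected_survival(curves[curves$arm == 1, ])
      )
      list(network = net, baseline = base, curves = curves,
           expected_survival = exp_surv,
           accumulated = accumulate_weights(net))
    })
    cox[[oc]] <- stage(paste0("cox_", oc), {
      fit <- fit_weighted_cox(design_x_nondegenerate(prop$design),
                              cohort[[tcol]], cohort[[ecol]],
                              weights = prop$weights,
                              treatment = cohort$treatment)
      list(fit = fit, ph_test = proportionality_test(fit))
    })
  }

  boot <- NULL
  if (config$B > 0) {
    boot <- stage("bootstrap", {
      bc <- bootstrap_config(
        outcome = config$bootstrap_outcome,
        hidden_ps = config$hidden_ps, hidden_surv = config$hidden_surv,
        lr_ps = if (length(config$lr_grid_ps) == 1) config$lr_grid_ps else
          prop$model$lr,
        lr_surv = if (length(config$lr_grid_surv) == 1) config$lr_grid_surv
          else survival[[config$bootstrap_outcome]]$network$lr,
        epochs_ps = max(20L, config$epochs_ps %/% 2L),
        epochs_surv = max(20L, config$epochs_surv %/% 2L),
        clip = config$clip
      )
      reps <- run_bootstrap(cohort, B = config$B, config = bc,
                            base_seed = config$seed)
      list(replicates = reps, summary = summarize_bootstrap(reps))
    })
  }

  manifest <- list(
    config_hash = config_hash(config),
    seed = config$seed,
    n_claims = nrow(claims),
    n_cohort = nrow(cohort),
    package_version = as.character(utils::packageVersion("emulsurv")),
    r_version = R.version.string,
    timestamp_free = TRUE   # manifest is rerun-stable: no clock fields
  )

  structure(
    list(claims = claims, exclusion_log = assembled$log,
         imputed_fraction = assembled$imputed_fraction, cohort = cohort,
         descriptives = descriptives, propensity = prop,
         survival = survival, cox = cox, bootstrap = boot,
         ground_truth = ground_truth, manifest = manifest),
    class = "emulation_bundle"
  )
}

#' Render a human-readable report from a pipeline bundle
#'
#' Prints (and invisibly returns) the report tables: the descriptive table,
#' per-arm unadjusted incidences, expected survival per outcome, the Cox
#' comparator with its proportionality test, and the bootstrap forest table.
#' Every number is taken from the bundle's stage outputs; nothing is
#' recomputed here.
#'
#' @param bundle An `emulation_bundle`.
#' @param quiet Suppress printing.
#' @return Invisible list of tibbles: `descriptives`, `incidence`,
#'   `expected_survival`, `cox`, `forest`.
#' @export
report_bundle <- function(bundle, quiet = FALSE) {
  stopifnot(inherits(bundle, "emulation_bundle"))
  desc <- bundle$descriptives
  incidence <- desc[desc$type == "outcome", , drop = FALSE]

  exp_surv <- purrr::imap(bundle$survival, function(s, oc) {
    ev <- paste0("event_", oc)
    n_event <- sum(bundle$cohort[[ev]])
    tibble(outcome = oc, arm0_days = s$expected_survival[["arm0"]],
           arm1_days = s$expected_survival[["arm1"]],
           analyzable = n_event > 0)
  }) |> bind_rows()

  cox_tab <- purrr::imap(bundle$cox, function(cf, oc) {
    mutate(tidy(cf$fit), outcome = oc, .before = 1)
  }) |> bind_rows()

  forest <- if (!is.null(bundle$bootstrap)) {
    bundle$bootstrap$summary$weights
  } else {
    tibble(feature = character(), q25 = double(), median = double(),
           q75 = double())
  }

  if (!quiet) {
    cat("== Cohort ==\n")
    cat("claims in:", bundle$manifest$n_claims,
        "| analysis cohort:", bundle$manifest$n_cohort, "\n")
    print(bundle$exclusion_log)
    cat("\n== Descriptive table ==\n")
    print(as_tibble(desc), n = 15)
    cat("\n== Unadjusted incidence ==\n")
    print(incidence)
    cat("\n== Expected survival (days) ==\n")
    print(exp_surv)
    cat("\n== Weighted Cox comparator ==\n")
    print(cox_tab)
    if (nrow(forest) > 0) {
      cat("\n== Bootstrap forest table (accumulated weights) ==\n")
      print(forest, n = 30)
    }
  }
  invisible(list(descriptives = desc, incidence = incidence,
                 expected_survival = exp_surv, cox = cox_tab,
                 forest = forest))
}
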