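# broom-style tidiers for the fitted objects.

#' Tidy a weighted Cox fit
#'
#' @param x A `cox_fit`.
#' @param robust Use sandwich standard errors for the test statistic
#'   (default TRUE, the honest choice under IPT weighting).
#' @param ... Unused.
#' @return Tibble with `term`, `estimate` (log hazard ratio), `std.error`,
#'   `robust.se`, `statistic`, `p.value`.
#' @method tidy cox_fit
#' @export
tidy.cox_fit <- function(x, robust = TRUE, ...) {
  se <- if (robust) x$robust_se else x$se
  stat <- x$coefficients / se
  tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = unname(x$se),
    robust.se = unname(x$robust_se),
    statistic = unname(stat),
    p.value = unname(2 * stats::pnorm(-abs(stat)))
  )
}

#' @rdname tidy.cox_fit
#' @method glance cox_fit
#' @export
glance.cox_fit <- function(x, ...) {
  tibble(n = x$n, nevent = x$nevent, logLik = x$loglik, iter = x$iter,
         converged = x$converged)
}

#' Tidy a survival network: layer-accumulated input weights
#'
#' @param x A `survival_network`.
#' @param ... Unused.
#' @return Tibble with `term` and `accumulated_weight` (the linearized
#'   per-input effect, treatment indicator included).
#' @method tidy survival_network
#' @export
tidy.survival_network <- function(x, ...) {
  w <- accumulate_weights(x)
  tibble(term = names(w) %||% paste0("x", seq_along(w)),
         accumulated_weight = unname(w))
}

#' @rdname tidy.survival_network
#' @method glance survival_network
#' @export
glance.survival_network <- function(x, ...) {
  tibble(hidden = paste(x$hidden, collapse = "x"), lr = x$lr,
         epochs = x$epochs, best_epoch = x$best_epoch,
         final_loss = x$final_loss, risk_set = x$risk_set)
}

#' Tidy a propensity model: accumulated input weights
#'
#' @param x A `propensity_model`.
#' @param ... Unused.
#' @return Tibble with `term` and `accumulated_weight` on the logit scale.
#' @method tidy propensity_model
#' @export
tidy.propensity_model <- function(x, ...) {
  w <- accumulate_weights(x)
  nms <- if (!is.null(x$col_map)) {
    x$col_map$column[!is.na(x$col_map$column)]
  } else NULL
  tibble(term = nms %||% paste0("x", seq_along(w)),
         accumulated_weight = unname(w))
}

#' @rdname tidy.propensity_model
#' @method glance propensity_model
#' @export
glance.propensity_model <- function(x, ...) {
  tibble(hidden = x$hidden, lr = x$lr, final_loss = x$final_loss,
         best_epoch = x$best_epoch)
}

#' Tidy a bootstrap summary (forest-plot table)
#'
#' @param x A `bootstrap_summary`.
#' @param ... Unused.
#' @return The per-feature quantile tibble (`feature`, `q25`, `median`,
#'   `q75`).
#' @method tidy bootstrap_summary
#' @export
tidy.bootstrap_summary <- function(x, ...) x$weights

#' @rdname tidy.bootstrap_summary
#' @method glance bootstrap_summary
#' @export
glance.bootstrap_summary <- function(x, ...) {
  tibble(B_success = x$B_success, n_failed = x$n_failed)
}
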