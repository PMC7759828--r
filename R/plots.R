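# ggplot2 graphics for the result objects.

#' Plot marginal survival curves (optionally with bootstrap bands)
#'
#' @param curves Tibble from [marginal_survival_curves()] (columns `arm`,
#'   `time`, `surv`).
#' @param bands Optional `bands` tibble from a `bootstrap_summary`
#'   (columns `arm`, `time`, `lower`, `upper`).
#' @param arm_labels Length-2 labels for arms 0 and 1.
#' @return A ggplot.
#' @export
plot_survival_curves <- function(curves, bands = NULL,
                                 arm_labels = c("open repair",
                                                "endovascular repair")) {
  curves <- mutate(curves, arm_f = factor(.data$arm, levels = c(0, 1),
                                          labels = arm_labels))
  p <- ggplot2::ggplot(curves,
                       ggplot2::aes(.data$time, .data$surv,
                                    colour = .data$arm_f)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "days since treatment", y = "survival probability",
                  colour = NULL) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::theme_minimal()
  if (!is.null(bands)) {
    bands <- mutate(bands, arm_f = factor(.data$arm, levels = c(0, 1),
                                          labels = arm_labels))
    p <- p + ggplot2::geom_ribbon(
      data = bands,
      ggplot2::aes(x = .data$time, ymin = .data$lower, ymax = .data$upper,
                   fill = .data$arm_f),
      alpha = 0.2, inherit.aes = FALSE
    ) + ggplot2::labs(fill = NULL)
  }
  p
}

#' @method autoplot survival_curve
#' @export
autoplot.survival_curve <- function(object, ...) {
  df <- mutate(as_tibble(object), arm = attr(object, "arm") %||% NA)
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$surv)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "days since treatment", y = "survival probability") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::theme_minimal()
}

#' Forest plot of bootstrap-accumulated effect weights
#'
#' Median and 25--75% quantile interval of each input's accumulated weight
#' across bootstrap replicates; negative values indicate lower hazard.
#'
#' @param object A `bootstrap_summary`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot bootstrap_summary
#' @export
autoplot.bootstrap_summary <- function(object, ...) {
  df <- arrange(object$weights, .data$median)
  df$feature <- factor(df$feature, levels = df$feature)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$median, y = .data$feature)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$q25,
                                          xmax = .data$q75)) +
    ggplot2::labs(x = "accumulated weight (median, 25-75%)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Love plot of covariate balance before and after IPT weighting
#'
#' @param object A `balance_table` from [balance_diagnostics()].
#' @param threshold Reference line (default 0.1, the conventional SMD bound).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot balance_table
#' @export
autoplot.balance_table <- function(object, threshold = 0.1, ...) {
  df <- tidyr::pivot_longer(
    as_tibble(object), c("smd_unweighted", "smd_weighted"),
    names_to = "stage", values_to = "smd", names_prefix = "smd_"
  )
  ord <- arrange(object, .data$smd_unweighted)$column
  df$column <- factor(df$column, levels = ord)
  ggplot2::ggplot(df, ggplot2::aes(x = abs(.data$smd), y = .data$column,
                                   colour = .data$stage)) +
    ggplot2::geom_vline(xintercept = threshold, linetype = 2,
                        colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "|standardized mean difference|", y = NULL,
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Propensity-score overlap plot
#'
#' @param scores Propensity scores.
#' @param treatment Binary treatment vector.
#' @param arm_labels Length-2 labels for arms 0 and 1.
#' @return A ggplot histogram pair.
#' @export
plot_propensity_overlap <- function(scores, treatment,
                                    arm_labels = c("open repair",
                                                   "endovascular repair")) {
  df <- tibble(score = scores,
               arm = factor(treatment, levels = c(0, 1),
                            labels = arm_labels))
  ggplot2::ggplot(df, ggplot2::aes(.data$score, fill = .data$arm)) +
    ggplot2::geom_histogram(alpha = 0.5, position = "identity", bins = 40) +
    ggplot2::labs(x = "propensity score", y = "subjects", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
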