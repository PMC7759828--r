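# IPT-weighted deep survival network: partial-likelihood-style loss,
# full-batch Adam training with a cyclical learning rate, weighted Breslow
# baseline hazard, counterfactual marginal survival curves, restricted mean
# survival, and layer-accumulated effect weights.

# Risk-set bookkeeping shared by the loss, the Cox fit and the Breslow
# estimator. Returns, for data sorted by ascending observed time, the suffix
# index at which each subject's risk set starts (Breslow tie handling: all
# subjects with Y_j >= Y_i for risk_set = "ge"; strictly later times for the
# literal "gt" reading).
risk_set_starts <- function(time_sorted, risk_set = c("ge", "gt")) {
  risk_set <- match.arg(risk_set)
  n <- length(time_sorted)
  first_of_group <- which(!duplicated(time_sorted))
  group_id <- cumsum(!duplicated(time_sorted))
  if (risk_set == "ge") {
    first_of_group[group_id]
  } else {
    # start of the NEXT tie group; n + 1 marks an empty risk set
    nxt <- c(first_of_group[-1], n + 1L)
    nxt[group_id]
  }
}

# Loss and gradient of the weighted partial-likelihood objective
#   l = -(1 / sum(d)) * sum_i d_i w_i [ g_i - log sum_{j in R_i} v_j exp(g_j) ]
# where v_j = 1 under the displayed loss and v_j = w_j under the fully
# weighted (pseudo-population) variant.
cox_pl_grad <- function(g, time, status, w, risk_set = "ge",
                        weight_denominator = FALSE, grad = TRUE) {
  n <- length(g)
  stopifnot(length(time) == n, length(status) == n, length(w) == n)
  nd <- sum(status)
  if (nd == 0) abort("weighted_loss is undefined with zero events (division by sum of d).")

  ord <- order(time)
  g_s <- g[ord]; t_s <- time[ord]; d_s <- status[ord]; w_s <- w[ord]
  v_s <- if (weight_denominator) w_s else rep(1, n)

  gmax <- max(g_s)
  r_s <- v_s * exp(g_s - gmax)
  suffix <- rev(cumsum(rev(r_s)))
  starts <- risk_set_starts(t_s, risk_set)
  denom <- ifelse(starts <= n, suffix[pmin(starts, n)], 0)

  ev <- d_s == 1
  empty <- ev & denom <= 0
  if (any(empty)) {
    warn(sprintf("%d event(s) with an empty risk set dropped from the loss (risk_set = 'gt')",
                 sum(empty)))
    ev <- ev & !empty
  }
  log_denom <- log(denom[ev]) + gmax
  loss <- -sum(w_s[ev] * (g_s[ev] - log_denom)) / nd

  out <- list(loss = loss)
  if (grad) {
    # a_i = d_i w_i / denom_i accumulated over events whose risk set
    # contains subject k: events with t_i <= Y_k ("ge") or t_i < Y_k ("gt").
    a <- numeric(n)
    a[ev] <- w_s[ev] / denom[ev]
    csum <- cumsum(a)
    group_id <- cumsum(!duplicated(t_s))
    last_of_group <- c(which(!duplicated(t_s))[-1] - 1L, n)
    A <- if (risk_set == "ge") {
      csum[last_of_group[group_id]]
    } else {
      first <- risk_set_starts(t_s, "ge")
      ifelse(first > 1L, csum[pmax(first - 1L, 1L)], 0)
    }
    event_term <- d_s * w_s
    event_term[empty] <- 0           # dropped events contribute no term
    grad_s <- -(event_term - r_s * A) / nd
    gr <- numeric(n)
    gr[ord] <- grad_s
    out$grad <- gr
  }
  out
}

#' Weighted partial-likelihood loss for a survival network
#'
#' Evaluates the IPT-weighted objective
#' \deqn{l = -\frac{1}{\sum_i d_i} \sum_i d_i w_i \left[ g_i - \log
#'   \sum_{j \in R_i} \exp(g_j) \right]}{
#'   l = -(1/sum d) sum_i d_i w_i [g_i - log sum_{j in R_i} exp(g_j)]}
#' where `g` is the network output per subject and `R_i` the at-risk set at
#' subject i's observed time. Risk sets are built on observed times with
#' Breslow tie handling and include the event subject (`risk_set = "ge"`);
#' the literal strict-inequality reading is available as `risk_set = "gt"`.
#' Weights multiply the event terms only, as displayed;
#' `weight_denominator = TRUE` switches to the fully weighted
#' pseudo-population form used by weighted Cox software.
#'
#' @param g Network output vector (one finite scalar per subject).
#' @param time Observed times `Y = min(T, C)`.
#' @param status Event indicators `d` in \{0, 1\}; at least one event.
#' @param weights IPT weights (default all 1).
#' @param risk_set `"ge"` (default) or `"gt"`.
#' @param weight_denominator Use weights inside the log-sum (default FALSE).
#' @return The scalar loss.
#' @export
weighted_loss <- function(g, time, status, weights = NULL,
                          risk_set = c("ge", "gt"),
                          weight_denominator = FALSE) {
  risk_set <- match.arg(risk_set)
  w <- weights %||% rep(1, length(g))
  cox_pl_grad(g, time, status, w, risk_set, weight_denominator,
              grad = FALSE)$loss
}

survival_net_forward_loss <- function(layers, x, time, status, w, risk_set,
                                      weight_denominator) {
  g <- nn_predict(layers, x)
  cox_pl_grad(g, time, status, w, risk_set, weight_denominator, grad = FALSE)$loss
}

train_survival_net <- function(x, time, status, w, hidden, lr, epochs,
                               schedule, cycle_period, cycle_decay, seed,
                               risk_set, weight_denominator,
                               x_val = NULL, time_val = NULL,
                               status_val = NULL, w_val = NULL) {
  sizes <- c(ncol(x), hidden, 1L)
  layers <- nn_init(sizes, seed)
  state <- adam_state(layers)
  best <- list(layers = layers, loss = Inf, epoch = 0L)
  trace <- vector("list", epochs)
  monitor_val <- !is.null(x_val)
  for (ep in seq_len(epochs)) {
    lr_ep <- lr_schedule(schedule, ep, lr, cycle_period, cycle_decay)
    acts <- nn_forward(layers, x)
    g <- drop(acts[[length(acts)]])
    pl <- cox_pl_grad(g, time, status, w, risk_set, weight_denominator)
    if (!is.finite(pl$loss)) {
      abort(sprintf(
        "survival training diverged (non-finite loss) at epoch %d, lr %g, hidden [%s]",
        ep, lr, paste(hidden, collapse = ", ")))
    }
    grads <- nn_backward(layers, acts, pl$grad)
    st <- adam_step(layers, grads, state, lr_ep)
    layers <- st$layers
    state <- st$state
    mon <- if (monitor_val) {
      survival_net_forward_loss(layers, x_val, time_val, status_val, w_val,
                                risk_set, weight_denominator)
    } else {
      pl$loss
    }
    trace[[ep]] <- tibble(epoch = ep, lr = lr_ep, train_loss = pl$loss,
                          monitor_loss = mon)
    if (is.finite(mon) && mon < best$loss - 1e-12) {
      best <- list(layers = layers, loss = mon, epoch = ep)
    }
  }
  list(layers = best$layers, loss = best$loss, epoch = best$epoch,
       trace = bind_rows(compact(trace)))
}

#' Fit the IPT-weighted deep survival network
#'
#' Trains a fully connected network `g(X, Z)` (rectifier hidden layers,
#' linear scalar output; the treatment indicator is the last input column)
#' by full-batch Adam on [weighted_loss()]. The learning rate follows a
#' triangular cyclical schedule between `lr/4` and `lr` with period
#' `cycle_period` epochs whose amplitude decays by `cycle_decay` per cycle,
#' so early epochs
#' explore and late epochs settle. When `lr_grid` has several values the
#' rate is selected by held-out loss on a `val_fraction` split, then the
#' network is refit on all data. `hidden = integer(0)` gives a linear model
#' in the inputs, which coincides with a weighted Cox fit of the same
#' objective (see [fit_weighted_cox()]).
#'
#' @param design `design_matrix` or numeric covariate matrix.
#' @param treatment Binary treatment vector (appended as the last input).
#' @param time,status Observed times and event indicators.
#' @param weights IPT weights (default 1).
#' @param hidden Integer vector of hidden widths (default `c(32, 16)`).
#' @param lr_grid Learning-rate grid (default 4 values log-spaced on
#'   0.004--0.04).
#' @param epochs Training epochs (default 200).
#' @param schedule `"cyclical"` (default) or `"constant"`.
#' @param cycle_period,cycle_decay Cyclical schedule parameters.
#' @param val_fraction Held-out fraction for grid selection (default 0.2).
#' @param seed Integer seed.
#' @param risk_set,weight_denominator Passed to [weighted_loss()].
#' @return Object of class `survival_network`: layer weights, input map,
#'   training metadata and trace.
#' @export
fit_survival_network <- function(design, treatment, time, status,
                                 weights = NULL,
                                 hidden = c(32L, 16L),
                                 lr_grid = exp(seq(log(0.004), log(0.04),
                                                   length.out = 4)),
                                 epochs = 200L,
                                 schedule = c("cyclical", "constant"),
                                 cycle_period = 20L,
                                 cycle_decay = 0.9,
                                 val_fraction = 0.2,
                                 seed = 1L,
                                 risk_set = c("ge", "gt"),
                                 weight_denominator = FALSE) {
  schedule <- match.arg(schedule)
  risk_set <- match.arg(risk_set)
  x <- design_x(design)
  z <- as.numeric(treatment)
  w <- weights %||% rep(1, nrow(x))
  if (length(unique(z)) < 2) abort("both treatment arms are required.")
  if (sum(status) < 1) abort("at least one event is required.")
  xz <- cbind(x, treatment = z)
  hidden <- as.integer(hidden)

  seeds <- derive_seeds(seed, 3L)
  grid_trace <- NULL
  lr <- lr_grid[1]
  if (length(lr_grid) > 1) {
    n <- nrow(xz)
    val_idx <- with_seed(seeds[1], sample.int(n, max(2L, round(val_fraction * n))))
    tr_idx <- setdiff(seq_len(n), val_idx)
    ok_split <- sum(status[tr_idx]) > 0 && sum(status[val_idx]) > 0 &&
      length(unique(z[tr_idx])) == 2
    val_losses <- map_dbl(lr_grid, function(l) {
      if (!ok_split) return(NA_real_)
      fit <- train_survival_net(
        xz[tr_idx, , drop = FALSE], time[tr_idx], status[tr_idx], w[tr_idx],
        hidden, l, epochs, schedule, cycle_period, cycle_decay, seeds[2],
        risk_set, weight_denominator,
        x_val = xz[val_idx, , drop = FALSE], time_val = time[val_idx],
        status_val = status[val_idx], w_val = w[val_idx]
      )
      fit$loss
    })
    if (all(is.na(val_losses))) {
      lr <- lr_grid[1]
    } else {
      lr <- lr_grid[which.min(val_losses)]
    }
    grid_trace <- tibble(lr = lr_grid, val_loss = val_losses)
  }

  fit <- train_survival_net(
    xz, time, status, w, hidden, lr, epochs, schedule, cycle_period,
    cycle_decay, seeds[3], risk_set, weight_denominator
  )

  structure(
    list(
      layers = fit$layers,
      hidden = hidden,
      activation = c(hidden = "relu", output = "linear"),
      input_map = colnames(xz),
      treatment_index = ncol(xz),
      lr = lr,
      grid = grid_trace,
      schedule = schedule,
      cycle_period = cycle_period,
      cycle_decay = cycle_decay,
      epochs = epochs,
      final_loss = fit$loss,
      best_epoch = fit$epoch,
      trace = fit$trace,
      seed = seed,
      risk_set = risk_set,
      weight_denominator = weight_denominator
    ),
    class = "survival_network"
  )
}

#' @export
print.survival_network <- function(x, ...) {
  cat("<survival_network> hidden [", paste(x$hidden, collapse = ", "),
      "] | lr ", signif(x$lr, 3), " | loss ", signif(x$final_loss, 5),
      " | best epoch ", x$best_epoch, "\n", sep = "")
  invisible(x)
}

#' Network risk score for given covariates and treatment
#'
#' @param network A `survival_network`.
#' @param design `design_matrix` or matrix.
#' @param treatment Treatment values (scalar or per-row vector).
#' @return Numeric vector `g(X, Z)`.
#' @export
predict_risk_score <- function(network, design, treatment) {
  x <- design_x(design)
  z <- rep_len(as.numeric(treatment), nrow(x))
  xz <- cbind(x, treatment = z)
  if (ncol(xz) != nrow(network$layers[[1]]$W)) {
    abort("design does not match the network's input dimension.")
  }
  nn_predict(network$layers, xz)
}

#' Weighted Breslow baseline cumulative hazard
#'
#' Nonparametric baseline hazard under the fitted network: the increment at
#' each distinct event time t is
#' `sum(w over events at t) / sum(w * exp(g) over subjects at risk at t)`,
#' and the cumulative hazard is their running sum. Doubling all weights
#' leaves the increments unchanged.
#'
#' @param network A fitted `survival_network` (or `NULL` with `g` supplied).
#' @param design,treatment Inputs at which to evaluate the network.
#' @param time,status Observed times and event indicators.
#' @param weights IPT weights (default 1).
#' @param g Optional precomputed risk scores (overrides the network).
#' @return Tibble of class `baseline_hazard`: `time`, `increment`, `cumhaz`
#'   at the ordered distinct event times.
#' @export
breslow_baseline <- function(network, design, treatment, time, status,
                             weights = NULL, g = NULL) {
  w <- weights %||% rep(1, length(time))
  if (is.null(g)) g <- predict_risk_score(network, design, treatment)
  ord <- order(time)
  t_s <- time[ord]; d_s <- status[ord]; w_s <- w[ord]; g_s <- g[ord]
  r_s <- w_s * exp(g_s)
  suffix <- rev(cumsum(rev(r_s)))
  starts <- risk_set_starts(t_s, "ge")
  ev_times <- unique(t_s[d_s == 1])
  inc <- map_dbl(ev_times, function(tt) {
    idx <- which(t_s == tt)
    sum(w_s[idx][d_s[idx] == 1]) / suffix[starts[idx[1]]]
  })
  out <- tibble(time = ev_times, increment = inc, cumhaz = cumsum(inc))
  class(out) <- c("baseline_hazard", class(out))
  out
}

#' Counterfactual marginal survival curve for one arm
#'
#' Standardizes over the cohort: every subject's treatment input is set to
#' `arm`, each subject's survival function is
#' `S_i(t) = exp(-H0(t) * exp(g(X_i, arm)))` under the Breslow baseline
#' `H0`, and the marginal curve is the average of the `S_i`. This targets
#' the same marginal estimand as the IPT weighting.
#'
#' @param network Fitted `survival_network`.
#' @param baseline `baseline_hazard` from [breslow_baseline()].
#' @param design `design_matrix` or matrix of the standardization population.
#' @param arm 0 or 1.
#' @return Tibble of class `survival_curve` with `time` (starting at 0) and
#'   `surv`; attribute `arm`.
#' @export
marginal_survival_curve <- function(network, baseline, design, arm) {
  if (!arm %in% c(0, 1)) abort("`arm` must be 0 or 1.")
  g <- predict_risk_score(network, design, arm)
  hr <- exp(g - max(g))
  scale_back <- exp(max(g))
  # S(t) averaged over subjects at each baseline time
  surv <- map_dbl(baseline$cumhaz, function(H) mean(exp(-H * scale_back * hr)))
  out <- tibble(time = c(0, baseline$time), surv = c(1, surv))
  class(out) <- c("survival_curve", class(out))
  attr(out, "arm") <- arm
  out
}

#' Marginal survival curves for both arms on a common grid
#'
#' @inheritParams marginal_survival_curve
#' @return Tibble with columns `arm`, `time`, `surv`.
#' @export
marginal_survival_curves <- function(network, baseline, design) {
  bind_rows(
    mutate(as_tibble(marginal_survival_curve(network, baseline, design, 0)),
           arm = 0L, .before = 1),
    mutate(as_tibble(marginal_survival_curve(network, baseline, design, 1)),
           arm = 1L, .before = 1)
  )
}

#' Expected (restricted mean) survival time
#'
#' Trapezoidal integral of the survival curve over `[0, horizon]` — the
#' restricted mean survival time, in days.
#'
#' @param curve A `survival_curve` (tibble with `time`, `surv`).
#' @param horizon Upper limit in days; defaults to the last grid time and
#'   may not exceed it.
#' @return Expected survival in days.
#' @export
expected_survival <- function(curve, horizon = NULL) {
  tt <- curve$time
  ss <- curve$surv
  horizon <- horizon %||% max(tt)
  if (horizon <= 0) abort("`horizon` must be positive.")
  if (horizon > max(tt)) abort("`horizon` exceeds the curve's time grid.")
  keep <- tt <= horizon
  tt_k <- tt[keep]
  ss_k <- ss[keep]
  if (max(tt_k) < horizon) {
    # linear interpolation at the horizon
    s_h <- stats::approx(tt, ss, xout = horizon, ties = "ordered")$y
    tt_k <- c(tt_k, horizon)
    ss_k <- c(ss_k, s_h)
  }
  sum(diff(tt_k) * (head(ss_k, -1) + tail(ss_k, -1)) / 2)
}

#' Layer-accumulated effect weights
#'
#' Multiplies the layer weight matrices across the network (biases and the
#' rectifier nonlinearity omitted — a linearization), yielding one overall
#' scalar weight per input feature, including the treatment indicator. For a
#' linear network this is exactly the coefficient vector; with hidden layers
#' it is the first-order effect measure summarised by the bootstrap.
#'
#' @param network A `survival_network` (or `propensity_model`).
#' @return Named numeric vector, one entry per input.
#' @export
accumulate_weights <- function(network) {
  w <- Reduce(`%*%`, lapply(network$layers, function(l) l$W))
  v <- drop(w)
  nms <- network$input_map %||%
    (if (!is.null(network$col_map)) {
      network$col_map$column[!is.na(network$col_map$column)]
    } else NULL)
  if (!is.null(nms) && length(nms) == length(v)) names(v) <- nms
  v
}
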