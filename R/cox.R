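# Weighted Cox partial-likelihood fit by Newton-Raphson (Breslow ties) and a
# scaled-Schoenfeld proportional-hazards diagnostic. This is the linear
# comparator for the survival network and shares its weighting conventions.

# Log partial likelihood, score and information for the objective
#   L(b) = sum_i d_i w_i [ x_i b - log sum_{j in R_i} v_j exp(x_j b) ]
# with v = 1 (event-weighted, the network's convention) or v = w (fully
# weighted pseudo-population, coxph's convention). Breslow tie handling.
cox_pl_parts <- function(beta, x, time, status, w, weight_denominator,
                         need_info = TRUE, need_resid = FALSE) {
  n <- nrow(x)
  p <- ncol(x)
  ord <- order(time)
  x_s <- x[ord, , drop = FALSE]
  t_s <- time[ord]; d_s <- status[ord]; w_s <- w[ord]
  v_s <- if (weight_denominator) w_s else rep(1, n)

  eta <- drop(x_s %*% beta)
  emax <- max(eta)
  r <- v_s * exp(eta - emax)

  starts <- risk_set_starts(t_s, "ge")
  suffix_r <- rev(cumsum(rev(r)))
  suffix_rx <- apply(x_s * r, 2L, function(cc) rev(cumsum(rev(cc))))
  if (p == 1L) suffix_rx <- matrix(suffix_rx, ncol = 1L)

  S0 <- suffix_r[starts]                       # per-subject risk-set sums
  S1 <- suffix_rx[starts, , drop = FALSE]
  xbar <- S1 / S0

  ev <- which(d_s == 1)
  dw <- w_s[ev]
  loglik <- sum(dw * (eta[ev] - (log(S0[ev]) + emax)))
  score_resid_ev <- (x_s[ev, , drop = FALSE] - xbar[ev, , drop = FALSE])
  score <- colSums(dw * score_resid_ev)

  out <- list(loglik = loglik, score = score)

  if (need_info) {
    # S2 suffix sums over the p(p+1)/2 distinct second-moment columns
    pair_i <- rep(seq_len(p), times = seq_len(p))
    pair_j <- unlist(lapply(seq_len(p), function(k) seq_len(k)))
    xx <- x_s[, pair_i, drop = FALSE] * x_s[, pair_j, drop = FALSE] * r
    suffix_xx <- apply(xx, 2L, function(cc) rev(cumsum(rev(cc))))
    if (length(pair_i) == 1L) suffix_xx <- matrix(suffix_xx, ncol = 1L)
    info <- matrix(0, p, p)
    S2ev <- suffix_xx[starts[ev], , drop = FALSE]
    for (k in seq_along(pair_i)) {
      a <- pair_i[k]; b <- pair_j[k]
      val <- sum(dw * (S2ev[, k] / S0[ev] - xbar[ev, a] * xbar[ev, b]))
      info[a, b] <- val
      info[b, a] <- val
    }
    out$info <- info
  }

  if (need_resid) {
    # score residuals U_i (for the sandwich variance):
    # U_i = d_i w_i (x_i - xbar(Y_i)) - v_i e^{eta_i} [x_i A(Y_i) - B(Y_i)]
    # with A(t) = sum_{events k: t_k <= t} d_k w_k / S0_k and B likewise
    # with xbar_k inside.
    a_vec <- numeric(n)
    a_vec[ev] <- dw / S0[ev]
    csumA <- cumsum(a_vec)
    b_mat <- matrix(0, n, p)
    b_mat[ev, ] <- (dw / S0[ev]) * xbar[ev, , drop = FALSE]
    csumB <- apply(b_mat, 2L, cumsum)
    if (p == 1L) csumB <- matrix(csumB, ncol = 1L)
    group_id <- cumsum(!duplicated(t_s))
    last_of_group <- c(which(!duplicated(t_s))[-1] - 1L, n)
    gl <- last_of_group[group_id]
    A_i <- csumA[gl]
    B_i <- csumB[gl, , drop = FALSE]
    U_s <- matrix(0, n, p)
    U_s[ev, ] <- dw * score_resid_ev
    # r * a_vec already carries consistent exp(-emax)/exp(emax) scaling
    U_s <- U_s - r * (x_s * A_i - B_i)
    U <- matrix(0, n, p)
    U[ord, ] <- U_s
    out$resid_score <- U
    # Schoenfeld residuals at events, on the original event ordering by time
    out$schoenfeld <- dw * score_resid_ev
    out$event_times <- t_s[ev]
  }
  out
}

#' Weighted Cox regression by Newton-Raphson
#'
#' Maximizes the IPT-weighted Cox partial likelihood with Breslow tie
#' handling by Newton-Raphson with step-halving. By default the weights
#' multiply the event terms only, matching [weighted_loss()] so that a
#' linear [fit_survival_network()] targets the same optimum;
#' `weight_denominator = TRUE` gives the fully weighted pseudo-population
#' partial likelihood that `survival::coxph(weights = )` maximizes. Both
#' model-based (inverse information) and robust sandwich standard errors are
#' reported; under weighting the sandwich form is the honest one.
#'
#' @param x Covariate matrix, data frame or `design_matrix` (no constant
#'   columns).
#' @param time,status Observed times and event indicators (at least one
#'   event).
#' @param weights Case/IPT weights (default 1).
#' @param treatment Optional binary vector appended as a `treatment` column.
#' @param weight_denominator See above (default `FALSE`).
#' @param max_iter,tol Newton iteration cap and convergence tolerance on the
#'   score norm.
#' @return Object of class `cox_fit`: `coefficients`, `se` (model-based),
#'   `robust_se`, `vcov`, `loglik`, `iter`, `converged`, plus the data
#'   needed by [proportionality_test()].
#' @export
fit_weighted_cox <- function(x, time, status, weights = NULL,
                             treatment = NULL, weight_denominator = FALSE,
                             max_iter = 50L, tol = 1e-9) {
  xm <- design_x(x)
  if (is.null(colnames(xm))) colnames(xm) <- paste0("x", seq_len(ncol(xm)))
  if (!is.null(treatment)) xm <- cbind(xm, treatment = as.numeric(treatment))
  storage.mode(xm) <- "double"
  if (sum(status) < 1) abort("at least one event is required.")
  const <- apply(xm, 2L, function(cc) max(cc) == min(cc))
  if (any(const)) {
    abort(paste0("constant column(s) in the design: ",
                 paste(colnames(xm)[const], collapse = ", ")))
  }
  w <- weights %||% rep(1, length(time))
  p <- ncol(xm)
  beta <- rep(0, p)
  parts <- cox_pl_parts(beta, xm, time, status, w, weight_denominator)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    step <- tryCatch(solve(parts$info, parts$score), error = function(e) {
      abort("singular information matrix in fit_weighted_cox.")
    })
    # step-halving until the log partial likelihood does not decrease
    halve <- 0L
    repeat {
      cand <- beta + step / 2^halve
      cand_parts <- cox_pl_parts(cand, xm, time, status, w,
                                 weight_denominator)
      if (is.finite(cand_parts$loglik) &&
          cand_parts$loglik >= parts$loglik - 1e-12) break
      halve <- halve + 1L
      if (halve > 30L) {
        abort("step-halving failed to improve the partial likelihood.")
      }
    }
    beta <- cand
    parts <- cand_parts
    if (sqrt(sum(parts$score^2)) < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    abort(sprintf("fit_weighted_cox did not converge in %d iterations.",
                  max_iter))
  }

  full <- cox_pl_parts(beta, xm, time, status, w, weight_denominator,
                       need_resid = TRUE)
  vc <- solve(full$info)
  meat <- crossprod(full$resid_score)
  robust <- vc %*% meat %*% vc
  names(beta) <- colnames(xm)

  structure(
    list(
      coefficients = beta,
      se = setNames(sqrt(diag(vc)), colnames(xm)),
      robust_se = setNames(sqrt(diag(robust)), colnames(xm)),
      vcov = vc,
      robust_vcov = robust,
      loglik = full$loglik,
      score = full$score,
      info = full$info,
      iter = iter,
      converged = converged,
      n = length(time),
      nevent = sum(status),
      weight_denominator = weight_denominator,
      data = list(x = xm, time = time, status = status, w = w)
    ),
    class = "cox_fit"
  )
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("<cox_fit> n =", x$n, ", events =", x$nevent,
      ", iterations =", x$iter, "\n")
  print(tibble(term = names(x$coefficients), estimate = x$coefficients,
               se = x$se, robust_se = x$robust_se))
  invisible(x)
}

#' Proportional-hazards diagnostic from scaled Schoenfeld residuals
#'
#' Tests whether each coefficient drifts with time by correlating the
#' (weighted) Schoenfeld residuals with the rank of the event time: with
#' centred ranks `u_k` and residuals `s_k`, the per-covariate statistic is
#' `z_j^2 * m / (sum(u^2) * I_jj)` with `z = sum_k u_k s_k`, `m` the event
#' count and `I` the information at the fit, referred to chi-squared(1); the
#' global statistic is `m / sum(u^2) * z' I^{-1} z` on p degrees of freedom.
#' A small p-value indicates a proportionality violation for that term.
#'
#' @param fit A converged `cox_fit`.
#' @return A list of class `ph_test`: `table` (tibble with per-covariate
#'   correlation, chi-squared and p-value), `global_chisq`, `global_df`,
#'   `global_p`. With fewer than 3 events the test is flagged undefined.
#' @export
proportionality_test <- function(fit) {
  stopifnot(inherits(fit, "cox_fit"))
  d <- fit$data
  parts <- cox_pl_parts(fit$coefficients, d$x, d$time, d$status, d$w,
                        fit$weight_denominator, need_info = TRUE,
                        need_resid = TRUE)
  s <- parts$schoenfeld
  m <- nrow(s)
  p <- ncol(s)
  if (m < 3) {
    out <- list(
      table = tibble(term = names(fit$coefficients), rho = NA_real_,
                     chisq = NA_real_, p_value = NA_real_),
      global_chisq = NA_real_, global_df = p, global_p = NA_real_,
      defined = FALSE
    )
    class(out) <- "ph_test"
    return(out)
  }
  g <- rank(parts$event_times)
  u <- g - mean(g)
  z <- drop(crossprod(u, s))
  su2 <- sum(u^2)
  info <- parts$info
  chisq_j <- z^2 * m / (su2 * diag(info))
  rho <- map_dbl(seq_len(p), function(j) {
    sj <- s[, j]
    if (sd(sj) == 0) 0 else stats::cor(u, sj)
  })
  global <- drop(m / su2 * t(z) %*% solve(info, z))
  out <- list(
    table = tibble(
      term = names(fit$coefficients),
      rho = rho,
      chisq = chisq_j,
      p_value = pchisq(chisq_j, 1, lower.tail = FALSE)
    ),
    global_chisq = global,
    global_df = p,
    global_p = pchisq(global, p, lower.tail = FALSE),
    defined = TRUE
  )
  class(out) <- "ph_test"
  out
}

#' @export
print.ph_test <- function(x, ...) {
  cat("<ph_test> global chisq =", signif(x$global_chisq, 4),
      "on", x$global_df, "df, p =", signif(x$global_p, 4), "\n")
  print(x$table)
  invisible(x)
}
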