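# Neural propensity-score estimation, IPT weights and balance diagnostics.

bce_loss <- function(z_logit, y, reduce = TRUE) {
  # binary cross-entropy on the logit scale (numerically stable)
  l <- -(y * log_expit(z_logit) + (1 - y) * log_expit(-z_logit))
  if (reduce) mean(l) else l
}

# One full pass of minibatch SGD + Nesterov over the data; returns layers,
# optimizer state, and the epoch's mean training loss.
ps_epoch <- function(layers, state, x, y, lr, batch_size, momentum) {
  n <- nrow(x)
  idx <- sample.int(n)
  loss_sum <- 0
  for (start in seq(1L, n, by = batch_size)) {
    b <- idx[start:min(start + batch_size - 1L, n)]
    acts <- nn_forward(layers, x[b, , drop = FALSE])
    logit <- drop(acts[[length(acts)]])
    loss_sum <- loss_sum + sum(bce_loss(logit, y[b], reduce = FALSE))
    d_out <- (expit(logit) - y[b]) / length(b)
    grads <- nn_backward(layers, acts, d_out)
    st <- sgd_nesterov_step(layers, grads, state, lr, momentum)
    layers <- st$layers
    state <- st$state
  }
  list(layers = layers, state = state, loss = loss_sum / n)
}

train_ps_net <- function(x, y, hidden, lr, epochs, batch_size, momentum,
                         patience, x_val = NULL, y_val = NULL, seed = NULL) {
  sizes <- c(ncol(x), if (hidden > 0) hidden, 1L)
  layers <- nn_init(sizes, seed)
  state <- sgd_nesterov_state(layers)
  best <- list(layers = layers, loss = Inf, epoch = 0L)
  trace <- vector("list", epochs)
  wait <- 0L
  monitor_val <- !is.null(x_val)
  for (ep in seq_len(epochs)) {
    res <- ps_epoch(layers, state, x, y, lr, batch_size, momentum)
    layers <- res$layers
    state <- res$state
    if (!is.finite(res$loss)) {
      abort(sprintf("propensity training diverged (NaN loss) at learning rate %g",
                    lr))
    }
    mon <- if (monitor_val) {
      bce_loss(nn_predict(layers, x_val), y_val)
    } else {
      res$loss
    }
    trace[[ep]] <- tibble(epoch = ep, train_loss = res$loss,
                          monitor_loss = mon)
    if (mon < best$loss - 1e-9) {
      best <- list(layers = layers, loss = mon, epoch = ep)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (!is.null(patience) && wait >= patience) break
    }
  }
  list(layers = best$layers, loss = best$loss, epoch = best$epoch,
       trace = bind_rows(compact(trace)))
}

#' Fit a neural-network propensity-score model
#'
#' Estimates `P(Z = 1 | X)` with a fully connected network: one rectifier
#' hidden layer (width `hidden`; `hidden = 0` gives a plain logistic model,
#' useful as an oracle against `glm`) and a sigmoid output trained on binary
#' cross-entropy with minibatch stochastic gradient descent and Nesterov
#' momentum. When `lr_grid` has several values, the learning rate is chosen
#' by held-out cross-entropy on a `val_fraction` split (fixed by `seed`),
#' after which the model is refit on all data at the selected rate. Training
#' stops early when the monitored loss has not improved for `patience`
#' epochs; the best-epoch weights are kept.
#'
#' @param design A `design_matrix` (or plain numeric matrix) of encoded
#'   covariates.
#' @param treatment Binary treatment vector (both arms must be present).
#' @param hidden Hidden-layer width (default 16; 0 = logistic).
#' @param lr_grid Learning-rate grid, default 5 values log-spaced on
#'   0.001--0.05.
#' @param epochs Maximum training epochs (default 200).
#' @param batch_size Minibatch size (default 256; use `nrow` for full-batch
#'   deterministic descent).
#' @param momentum Nesterov momentum coefficient (default 0.9).
#' @param patience Early-stopping patience in epochs (default 20; `NULL`
#'   disables).
#' @param val_fraction Held-out fraction for learning-rate selection
#'   (default 0.2).
#' @param seed Integer seed making the fit reproducible.
#' @return An object of class `propensity_model` with the layer weights, the
#'   selected learning rate, training trace, and the design's column map.
#' @export
fit_propensity <- function(design, treatment,
                           hidden = 16L,
                           lr_grid = exp(seq(log(0.001), log(0.05),
                                             length.out = 5)),
                           epochs = 200L,
                           batch_size = 256L,
                           momentum = 0.9,
                           patience = 20L,
                           val_fraction = 0.2,
                           seed = 1L) {
  x <- design_x(design)
  y <- as.numeric(treatment)
  stopifnot(length(y) == nrow(x))
  if (length(unique(y)) < 2) {
    abort("fit_propensity requires both treatment arms in the data.")
  }
  batch_size <- min(batch_size, nrow(x))

  seeds <- derive_seeds(seed, 3L)
  grid_trace <- NULL
  lr <- lr_grid[1]
  if (length(lr_grid) > 1) {
    n <- nrow(x)
    val_idx <- with_seed(seeds[1], sample.int(n, max(1L, round(val_fraction * n))))
    tr_idx <- setdiff(seq_len(n), val_idx)
    val_losses <- map_dbl(lr_grid, function(l) {
      fit <- with_seed(seeds[2], train_ps_net(
        x[tr_idx, , drop = FALSE], y[tr_idx], hidden, l, epochs, batch_size,
        momentum, patience,
        x_val = x[val_idx, , drop = FALSE], y_val = y[val_idx],
        seed = seeds[2]
      ))
      fit$loss
    })
    lr <- lr_grid[which.min(val_losses)]
    grid_trace <- tibble(lr = lr_grid, val_loss = val_losses)
  }

  fit <- with_seed(seeds[3], train_ps_net(
    x, y, hidden, lr, epochs, batch_size, momentum, patience, seed = seeds[3]
  ))

  structure(
    list(
      layers = fit$layers,
      hidden = hidden,
      activation = c(hidden = "relu", output = "sigmoid"),
      lr = lr,
      grid = grid_trace,
      final_loss = fit$loss,
      best_epoch = fit$epoch,
      trace = fit$trace,
      seed = seed,
      col_map = if (inherits(design, "design_matrix")) design$col_map else NULL
    ),
    class = "propensity_model"
  )
}

#' @export
print.propensity_model <- function(x, ...) {
  cat("<propensity_model> hidden width", x$hidden,
      "| lr", signif(x$lr, 3),
      "| loss", signif(x$final_loss, 4),
      "| best epoch", x$best_epoch, "\n")
  invisible(x)
}

#' Predict propensity scores
#'
#' @param model A `propensity_model`.
#' @param design A `design_matrix` (or matrix) encoded identically to the
#'   training design.
#' @return Numeric vector of scores in (0, 1), one per row.
#' @export
predict_propensity <- function(model, design) {
  x <- design_x(design)
  if (ncol(x) != nrow(model$layers[[1]]$W)) {
    abort(sprintf("design has %d columns but the model expects %d",
                  ncol(x), nrow(model$layers[[1]]$W)))
  }
  if (!is.null(model$col_map) && inherits(design, "design_matrix")) {
    expect <- model$col_map$column[!is.na(model$col_map$column)]
    got <- design$col_map$column[!is.na(design$col_map$column)]
    if (!identical(expect, got)) {
      abort("design column map does not match the model's training design.")
    }
  }
  expit(nn_predict(model$layers, x))
}

#' Compute inverse-probability-of-treatment weights
#'
#' `w = 1/e` for treated subjects and `w = 1/(1 - e)` for controls, after
#' clipping the score to `[clip, 1 - clip]`. Every weight is at least 1;
#' clipping bounds all weights by `1/clip`. `clip = 0` applies the literal
#' rule with no trimming.
#'
#' @param scores Propensity scores in (0, 1).
#' @param treatment Binary treatment vector.
#' @param clip Symmetric clipping threshold in `[0, 0.5)` (default 0.01).
#' @return Numeric weight vector.
#' @export
compute_ipt_weights <- function(scores, treatment, clip = 0.01) {
  if (length(clip) != 1 || !is.finite(clip) || clip < 0 || clip >= 0.5) {
    abort("`clip` must lie in [0, 0.5).")
  }
  if (any(scores <= 0 | scores >= 1)) {
    abort("propensity scores must lie strictly in (0, 1).")
  }
  e <- pmin(pmax(scores, clip), 1 - clip)
  ifelse(treatment == 1, 1 / e, 1 / (1 - e))
}

#' Standardized-mean-difference balance diagnostics
#'
#' For every encoded covariate column, the between-arm standardized mean
#' difference before and after IPT weighting: mean difference divided by the
#' pooled unweighted standard deviation (so the weighted and unweighted SMDs
#' share a denominator). Constant columns are reported as SMD 0 with a
#' degeneracy flag.
#'
#' @param design A `design_matrix` or numeric matrix.
#' @param treatment Binary treatment vector.
#' @param weights IPT weights (default all 1).
#' @return A tibble of class `balance_table`: `column`, `smd_unweighted`,
#'   `smd_weighted`, `degenerate`.
#' @export
balance_diagnostics <- function(design, treatment, weights = NULL) {
  x <- design_x(design)
  z <- as.numeric(treatment)
  w <- weights %||% rep(1, nrow(x))

  wmean <- function(v, wt) sum(v * wt) / sum(wt)
  one <- function(j) {
    v <- x[, j]
    s1 <- v[z == 1]
    s0 <- v[z == 0]
    pooled <- sqrt((var(s1) + var(s0)) / 2)
    degen <- !is.finite(pooled) || pooled == 0
    if (degen) {
      return(tibble(column = colnames(x)[j], smd_unweighted = 0,
                    smd_weighted = 0, degenerate = TRUE))
    }
    tibble(
      column = colnames(x)[j],
      smd_unweighted = (mean(s1) - mean(s0)) / pooled,
      smd_weighted = (wmean(s1, w[z == 1]) - wmean(s0, w[z == 0])) / pooled,
      degenerate = FALSE
    )
  }
  out <- bind_rows(map(seq_len(ncol(x)), one))
  class(out) <- c("balance_table", class(out))
  out
}
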