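# Minimal fully-connected network engine: He-initialised rectifier layers,
# manual backpropagation, SGD with Nesterov momentum, Adam, and a cyclical
# learning-rate schedule. Sized for the small tabular networks used here
# (tens of inputs, widths <= 64); everything is dense base-R matrix algebra.

nn_init <- function(sizes, seed = NULL) {
  # sizes: c(n_in, widths..., n_out). Returns list of (W, b) with W in x out.
  with_seed(seed, {
    lapply(seq_len(length(sizes) - 1L), function(l) {
      fan_in <- sizes[l]
      list(
        W = matrix(rnorm(fan_in * sizes[l + 1L], sd = sqrt(2 / fan_in)),
                   nrow = fan_in),
        b = rep(0, sizes[l + 1L])
      )
    })
  })
}

# Forward pass. Hidden layers use the rectifier; the output layer is linear
# (a sigmoid, when needed, is applied by the loss for numerical stability).
nn_forward <- function(layers, x) {
  L <- length(layers)
  a <- vector("list", L + 1L)
  a[[1L]] <- x
  for (l in seq_len(L)) {
    z <- sweep(a[[l]] %*% layers[[l]]$W, 2L, layers[[l]]$b, "+")
    a[[l + 1L]] <- if (l < L) pmax(z, 0) else z
  }
  a
}

nn_predict <- function(layers, x) {
  drop(nn_forward(layers, x)[[length(layers) + 1L]])
}

# Backpropagate dL/d(output) (n x 1 matrix or vector) through the stack.
# Returns gradients with the same shapes as `layers`.
nn_backward <- function(layers, acts, d_out) {
  L <- length(layers)
  grads <- vector("list", L)
  delta <- matrix(d_out, ncol = ncol(layers[[L]]$W))
  for (l in rev(seq_len(L))) {
    a_in <- acts[[l]]
    grads[[l]] <- list(W = crossprod(a_in, delta), b = colSums(delta))
    if (l > 1L) {
      # rectifier derivative: post-activation of layer l-1 is positive iff
      # its pre-activation was.
      delta <- (delta %*% t(layers[[l]]$W)) * (acts[[l]] > 0)
    }
  }
  grads
}

nn_flatten_dim <- function(layers) {
  sum(map_dbl(layers, function(l) length(l$W) + length(l$b)))
}

# --- optimizers -------------------------------------------------------------

# SGD with Nesterov momentum, operating on the (W, b) list in place.
sgd_nesterov_state <- function(layers) {
  lapply(layers, function(l) list(W = 0 * l$W, b = 0 * l$b))
}

sgd_nesterov_step <- function(layers, grads, state, lr, momentum = 0.9) {
  for (l in seq_along(layers)) {
    state[[l]]$W <- momentum * state[[l]]$W - lr * grads[[l]]$W
    state[[l]]$b <- momentum * state[[l]]$b - lr * grads[[l]]$b
    layers[[l]]$W <- layers[[l]]$W + momentum * state[[l]]$W - lr * grads[[l]]$W
    layers[[l]]$b <- layers[[l]]$b + momentum * state[[l]]$b - lr * grads[[l]]$b
  }
  list(layers = layers, state = state)
}

adam_state <- function(layers) {
  list(
    m = lapply(layers, function(l) list(W = 0 * l$W, b = 0 * l$b)),
    v = lapply(layers, function(l) list(W = 0 * l$W, b = 0 * l$b)),
    t = 0L
  )
}

adam_step <- function(layers, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (l in seq_along(layers)) {
    for (nm in c("W", "b")) {
      g <- grads[[l]][[nm]]
      state$m[[l]][[nm]] <- beta1 * state$m[[l]][[nm]] + (1 - beta1) * g
      state$v[[l]][[nm]] <- beta2 * state$v[[l]][[nm]] + (1 - beta2) * g^2
      mhat <- state$m[[l]][[nm]] / bc1
      vhat <- state$v[[l]][[nm]] / bc2
      layers[[l]][[nm]] <- layers[[l]][[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(layers = layers, state = state)
}

# Triangular cyclical learning rate oscillating between amp/4 and amp with a
# fixed period (in epochs); the amplitude decays after each completed cycle,
# floored at 1e-3 of the base rate, so late epochs take vanishing steps and
# the optimum is approached tightly rather than orbited.
cyclical_lr <- function(epoch, base_lr, period = 20L, decay = 0.9) {
  cycle <- (epoch - 1L) %/% period
  amp <- max(base_lr * decay^cycle, base_lr * 1e-3)
  pos <- ((epoch - 1L) %% period) / period        # in [0, 1)
  tri <- 1 - abs(2 * pos - 1)                     # 0 -> 1 -> 0
  amp / 4 + (amp - amp / 4) * tri
}

lr_schedule <- function(schedule, epoch, base_lr, period = 20L, decay = 0.9) {
  switch(schedule,
    cyclical = cyclical_lr(epoch, base_lr, period, decay),
    constant = base_lr,
    abort(sprintf("unknown learning-rate schedule '%s'", schedule))
  )
}
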