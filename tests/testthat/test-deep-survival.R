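# helper: a hand-built linear "network" with fixed weights
linear_network <- function(w, input_names = NULL) {
  structure(
    list(layers = list(list(W = matrix(w, ncol = 1), b = 0)),
         hidden = integer(0),
         input_map = input_names %||% c(paste0("x", seq_len(length(w) - 1)),
                                        "treatment"),
         treatment_index = length(w)),
    class = "survival_network"
  )
}

test_that("the loss vanishes for a lone event and equals log(n!)/n for all events", {
  expect_equal(weighted_loss(1.7, time = 5, status = 1), 0)
  for (n in c(3, 6, 10)) {
    expect_equal(weighted_loss(rep(0, n), seq_len(n), rep(1, n)),
                 sum(log(seq_len(n))) / n)
  }
})

test_that("the loss matches a hand-summed evaluation on the 3-subject fixture", {
  g <- c(0.5, -0.2, 0.1)
  l <- weighted_loss(g, time = c(1, 2, 3), status = c(1, 0, 1),
                     weights = c(2, 1, 1))
  hand <- -(1 / 2) * (
    2 * (0.5 - log(exp(0.5) + exp(-0.2) + exp(0.1))) +
      1 * (0.1 - log(exp(0.1)))
  )
  expect_equal(l, hand)
})

test_that("the literal strict-inequality risk set drops the last event", {
  g <- c(0.5, -0.2, 0.1)
  expect_warning(
    l <- weighted_loss(g, c(1, 2, 3), c(1, 0, 1), c(2, 1, 1),
                       risk_set = "gt"),
    "empty risk set"
  )
  hand <- -(1 / 2) * 2 * (0.5 - log(exp(-0.2) + exp(0.1)))
  expect_equal(l, hand)
})

test_that("the loss is invariant to shifting every output by a constant", {
  set.seed(2)
  for (rep in 1:5) {
    n <- 40
    g <- rnorm(n)
    tm <- rexp(n)
    st <- rbinom(n, 1, 0.6)
    st[1] <- 1
    w <- runif(n, 0.5, 3)
    shift <- rnorm(1, sd = 5)
    expect_equal(weighted_loss(g, tm, st, w),
                 weighted_loss(g + shift, tm, st, w), tolerance = 1e-10)
  }
})

test_that("scaling all weights scales the loss but not the optimum", {
  fx <- small_cox_fixture()
  expect_equal(
    2 * weighted_loss(fx$x[, 1], fx$time, fx$status, fx$w),
    weighted_loss(fx$x[, 1], fx$time, fx$status, 2 * fx$w)
  )
  f1 <- fit_weighted_cox(fx$x, fx$time, fx$status, weights = fx$w)
  f2 <- fit_weighted_cox(fx$x, fx$time, fx$status, weights = 2 * fx$w)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-8)
})

test_that("zero events is an explicit error", {
  expect_error(weighted_loss(c(0, 0), c(1, 2), c(0, 0)), "zero events")
})

test_that("the analytic loss gradient matches finite differences", {
  set.seed(3)
  n <- 25
  g <- rnorm(n)
  tm <- sample(c(1, 2, 3, 4, 5), n, replace = TRUE)  # ties on purpose
  st <- rbinom(n, 1, 0.7)
  st[1] <- 1
  w <- runif(n, 0.5, 2)
  for (wd in c(FALSE, TRUE)) {
    an <- emulsurv:::cox_pl_grad(g, tm, st, w, "ge", wd)$grad
    eps <- 1e-6
    num <- vapply(seq_len(n), function(k) {
      gp <- g; gp[k] <- gp[k] + eps
      gm <- g; gm[k] <- gm[k] - eps
      (weighted_loss(gp, tm, st, w, weight_denominator = wd) -
         weighted_loss(gm, tm, st, w, weight_denominator = wd)) / (2 * eps)
    }, numeric(1))
    expect_equal(an, num, tolerance = 1e-5)
  }
})

test_that("a linear survival network recovers the weighted Cox optimum", {
  fx <- small_cox_fixture()
  net <- fit_survival_network(fx$x, fx$z, fx$time, fx$status,
                              weights = fx$w, hidden = integer(0),
                              lr_grid = 0.05, epochs = 2500, seed = 3)
  ref <- fit_weighted_cox(fx$x, fx$time, fx$status, weights = fx$w,
                          treatment = fx$z)
  got <- unname(drop(net$layers[[1]]$W))
  expect_equal(got, unname(ref$coefficients), tolerance = 1e-3)
})

test_that("a treatment-only network recovers a known protective effect", {
  cfg <- sim_config(n_beneficiaries = 3000, seed = 23,
                    missingness_spec = list(covariates = 0),
                    ps_coefficients = c("(Intercept)" = 0),
                    survival_spec = list(
                      long = list(log_hr = log(0.7), beta = NULL),
                      short = list(log_hr = log(0.7), beta = NULL)))
  co <- simulate_cohort(cfg)$cohort
  x <- matrix(numeric(0), nrow = nrow(co), ncol = 0)
  net <- fit_survival_network(x, co$treatment, co$time_long, co$event_long,
                              hidden = integer(0), lr_grid = 0.05,
                              epochs = 2000, seed = 5)
  ref <- fit_weighted_cox(cbind(z = co$treatment), co$time_long,
                          co$event_long)
  est <- unname(drop(net$layers[[1]]$W))
  expect_equal(est, unname(ref$coefficients), tolerance = 1e-3)
  expect_true(abs(est - log(0.7)) <= 3 * ref$se)
})

test_that("Breslow baseline increments follow the weighted ratio rule", {
  # single event, g = 0, w = 1: increment 1/1
  b <- breslow_baseline(NULL, NULL, NULL, time = 3, status = 1,
                        weights = 1, g = 0)
  expect_equal(b$increment, 1)
  # hand fixture: times 1,2,3; d = 1,0,1; g = 0.5,-0.2,0.1; w = 2,1,1
  g <- c(0.5, -0.2, 0.1)
  w <- c(2, 1, 1)
  b <- breslow_baseline(NULL, NULL, NULL, time = c(1, 2, 3),
                        status = c(1, 0, 1), weights = w, g = g)
  h1 <- 2 / (2 * exp(0.5) + exp(-0.2) + exp(0.1))
  h3 <- 1 / exp(0.1)
  expect_equal(b$increment, c(h1, h3))
  expect_equal(b$cumhaz, cumsum(c(h1, h3)))
  # doubling the weights leaves increments unchanged
  b2 <- breslow_baseline(NULL, NULL, NULL, time = c(1, 2, 3),
                         status = c(1, 0, 1), weights = 2 * w, g = g)
  expect_equal(b2$increment, b$increment)
})

test_that("a null network yields identical arm curves equal to exp(-H0)", {
  set.seed(6)
  n <- 40
  x <- cbind(a = rnorm(n))
  tm <- rexp(n)
  st <- rbinom(n, 1, 0.7); st[1] <- 1
  net <- linear_network(c(0, 0), c("a", "treatment"))
  base <- breslow_baseline(net, x, rep(0:1, n / 2), tm, st)
  c0 <- marginal_survival_curve(net, base, x, 0)
  c1 <- marginal_survival_curve(net, base, x, 1)
  expect_equal(c0$surv, c1$surv)
  expect_equal(c0$surv, c(1, exp(-base$cumhaz)))
  # a valid survival function
  expect_equal(c0$surv[1], 1)
  expect_true(all(diff(c0$surv) <= 1e-12))
  expect_true(all(c0$surv >= 0 & c0$surv <= 1))
  expect_error(marginal_survival_curve(net, base, x, 2), "arm")
})

test_that("a protective treatment lifts the treated marginal curve", {
  set.seed(7)
  n <- 60
  x <- cbind(a = rnorm(n))
  z <- rep(0:1, n / 2)
  tm <- rexp(n, exp(0.3 * x[, 1] - 0.8 * z))
  st <- rep(1L, n)
  net <- linear_network(c(0.3, -0.8), c("a", "treatment"))
  base <- breslow_baseline(net, x, z, tm, st)
  c0 <- marginal_survival_curve(net, base, x, 0)
  c1 <- marginal_survival_curve(net, base, x, 1)
  expect_true(all(c1$surv >= c0$surv))
})

test_that("expected survival integrates the curve by trapezoids", {
  flat <- tibble::tibble(time = c(0, 50, 100), surv = c(1, 1, 1))
  expect_equal(expected_survival(flat, 100), 100)
  # exponential curve on a fine grid approaches its mean
  tt <- seq(0, 8000, by = 1)
  expo <- tibble::tibble(time = tt, surv = exp(-tt / 300))
  expect_equal(expected_survival(expo), 300, tolerance = 1e-2)
  # step to one half at tau/2: area 0.75 tau under trapezoidal reading of
  # the jump grid point pair
  step <- tibble::tibble(time = c(0, 50, 50, 100),
                         surv = c(1, 1, 0.5, 0.5))
  expect_equal(expected_survival(step, 100), 75)
  expect_error(expected_survival(flat, -1), "positive")
  expect_error(expected_survival(flat, 200), "exceeds")
})

test_that("accumulated weights multiply the layer matrices", {
  # identity single layer returns the input weights unchanged
  net1 <- linear_network(c(0.4, -0.7))
  expect_equal(unname(accumulate_weights(net1)), c(0.4, -0.7))
  # hand-multiplied two-layer product
  W1 <- matrix(c(1, 2, 3, 4), 2, 2)
  W2 <- matrix(c(0.5, -1), 2, 1)
  net2 <- structure(
    list(layers = list(list(W = W1, b = c(0, 0)), list(W = W2, b = 0)),
         input_map = c("a", "treatment")),
    class = "survival_network"
  )
  expect_equal(unname(accumulate_weights(net2)), drop(W1 %*% W2))
  # zeroed treatment column zeroes the treatment weight
  W1z <- W1; W1z[2, ] <- 0
  net3 <- structure(
    list(layers = list(list(W = W1z, b = c(0, 0)), list(W = W2, b = 0)),
         input_map = c("a", "treatment")),
    class = "survival_network"
  )
  expect_equal(accumulate_weights(net3)[["treatment"]], 0)
})

test_that("training rejects degenerate inputs with clear errors", {
  x <- matrix(rnorm(20), ncol = 2)
  expect_error(
    fit_survival_network(x, rep(1, 10), rexp(10), rep(1, 10)),
    "both treatment arms"
  )
  expect_error(
    fit_survival_network(x, rep(0:1, 5), rexp(10), rep(0, 10)),
    "at least one event"
  )
})
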