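test_that("continuous covariates are standardized with the population sd", {
  cohort <- tibble::tibble(age = c(70, 80, 90), sex = rep("male", 3))
  d <- encode_covariates(cohort, continuous = "age",
                         categorical = character(), binary = character())
  expect_equal(d$x[, "age"], c(-1.224744871, 0, 1.224744871),
               tolerance = 1e-8)
})

test_that("one-hot encoding uses the most frequent level as reference", {
  cohort <- tibble::tibble(
    race = c(rep("white", 5), rep("black", 3), rep("other", 2))
  )
  d <- encode_covariates(cohort, continuous = character(),
                         categorical = "race", binary = character())
  expect_equal(colnames(d$x), c("race_black", "race_other"))
  expect_equal(sum(d$x[, "race_black"]), 3)
  # transform mode reapplies the same encoding and rejects unseen levels
  d2 <- encode_covariates(tibble::tibble(race = "other"), design = d)
  expect_equal(drop(d2$x), c(race_black = 0, race_other = 1))
  expect_error(encode_covariates(tibble::tibble(race = "martian"),
                                 design = d), "unseen")
})

test_that("degenerate columns are flagged, not dropped silently", {
  cohort <- tibble::tibble(age = rep(77, 4), sex = rep("male", 4),
                           chf = c(0, 0, 0, 0))
  d <- encode_covariates(cohort, continuous = "age", categorical = "sex",
                         binary = "chf")
  cm <- d$col_map
  expect_true(cm$degenerate[cm$source == "age"])
  expect_true(cm$degenerate[cm$source == "sex"])
  expect_true(cm$degenerate[cm$source == "chf"])
  expect_true(all(d$x[, "age"] == 0))    # no NaN from zero sd
})

test_that("a zero-weight model scores everyone at one half", {
  x <- matrix(rnorm(20), ncol = 2)
  model <- structure(
    list(layers = list(list(W = matrix(0, 2, 1), b = 0)), hidden = 0L,
         col_map = NULL),
    class = "propensity_model"
  )
  expect_equal(predict_propensity(model, x), rep(0.5, 10))
  # determinism: a duplicated row gets an identical score
  x2 <- rbind(x, x[1, ])
  s <- predict_propensity(model, x2)
  expect_identical(s[11], s[1])
})

test_that("scores are monotone in a positive-weight linear model", {
  model <- structure(
    list(layers = list(list(W = matrix(2, 1, 1), b = -0.5)), hidden = 0L,
         col_map = NULL),
    class = "propensity_model"
  )
  xs <- matrix(seq(-2, 2, length.out = 9), ncol = 1)
  s <- predict_propensity(model, xs)
  expect_true(all(diff(s) > 0))
  expect_true(all(s > 0 & s < 1))
})

test_that("hidden width 0 reproduces the logistic-regression MLE", {
  set.seed(8)
  n <- 300
  x <- cbind(a = rnorm(n), b = rbinom(n, 1, 0.4))
  eta <- -0.3 + 0.8 * x[, 1] - 0.5 * x[, 2]
  y <- rbinom(n, 1, 1 / (1 + exp(-eta)))
  fit <- fit_propensity(x, y, hidden = 0, lr_grid = 0.5, epochs = 4000,
                        batch_size = n, patience = NULL, seed = 2)
  ref <- glm(y ~ x, family = binomial)
  got <- unname(c(drop(fit$layers[[1]]$W), fit$layers[[1]]$b))
  want <- unname(coef(ref)[c(2, 3, 1)])
  expect_equal(got, want, tolerance = 1e-3)
})

test_that("cross-entropy decreases monotonically on separable toy data", {
  x <- matrix(c(-2, -1, 1, 2), ncol = 1)
  y <- c(0, 0, 1, 1)
  fit <- fit_propensity(x, y, hidden = 0, lr_grid = 0.05, epochs = 60,
                        batch_size = 4, momentum = 0, patience = NULL,
                        seed = 1)
  expect_true(all(diff(fit$trace$train_loss) < 1e-10))
})

test_that("labels independent of covariates score near the treated fraction", {
  set.seed(12)
  n <- 1500
  x <- matrix(rnorm(2 * n), ncol = 2)
  y <- rbinom(n, 1, 0.3)
  fit <- fit_propensity(x, y, hidden = 4, lr_grid = 0.01, epochs = 60,
                        seed = 3)
  s <- predict_propensity(fit, x)
  expect_true(abs(mean(s) - mean(y)) < 0.05)
  expect_lt(sd(s), 0.1)
})

test_that("single-arm input is an error", {
  x <- matrix(rnorm(10), ncol = 1)
  expect_error(fit_propensity(x, rep(1, 10)), "both treatment arms")
})

test_that("IPT weights follow the inverse-score rule with clipping", {
  expect_equal(compute_ipt_weights(0.5, 1), 2)
  expect_equal(compute_ipt_weights(0.5, 0), 2)
  expect_equal(compute_ipt_weights(0.8, 1), 1.25)
  expect_equal(compute_ipt_weights(0.8, 0), 5)
  expect_equal(compute_ipt_weights(0.999, 0, clip = 0.01), 100)
  expect_error(compute_ipt_weights(0.5, 1, clip = 0.7), "0, 0.5")
  expect_error(compute_ipt_weights(1, 1), "strictly")
  # every weight in [1, 1/clip]
  set.seed(4)
  e <- runif(500, 1e-4, 1 - 1e-4)
  z <- rbinom(500, 1, 0.5)
  w <- compute_ipt_weights(e, z, clip = 0.02)
  expect_true(all(w >= 1 & w <= 1 / 0.02))
})

test_that("weighted pseudo-population size per arm is about n", {
  sim <- simulate_cohort(sim_config(n_beneficiaries = 4000, seed = 15,
                                    missingness_spec = list(covariates = 0)))
  co <- sim$cohort
  w <- compute_ipt_weights(sim$ground_truth$true_ps, co$treatment, clip = 0)
  n <- nrow(co)
  expect_true(abs(sum(w[co$treatment == 1]) - n) / n < 0.1)
  expect_true(abs(sum(w[co$treatment == 0]) - n) / n < 0.1)
})

test_that("balance diagnostics behave on identical arms and constants", {
  x <- cbind(a = rep(c(1, 2), 10), const = rep(1, 20))
  z <- rep(c(1, 0), each = 10)
  x[z == 0, "a"] <- x[z == 1, "a"]
  b <- balance_diagnostics(x, z)
  expect_equal(b$smd_unweighted[b$column == "a"], 0)
  expect_true(b$degenerate[b$column == "const"])
  expect_equal(b$smd_weighted[b$column == "const"], 0)
})

test_that("true-propensity IPT weights improve covariate balance", {
  sim <- simulate_cohort(sim_config(n_beneficiaries = 4000, seed = 16,
                                    missingness_spec = list(covariates = 0)))
  co <- sim$cohort
  d <- encode_covariates(co)
  w <- compute_ipt_weights(sim$ground_truth$true_ps, co$treatment)
  b <- balance_diagnostics(d, co$treatment, w)
  expect_lt(max(abs(b$smd_weighted)), max(abs(b$smd_unweighted)))
})
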