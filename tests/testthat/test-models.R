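test_that("standardisation centres, scales and is idempotent", {
  z <- standardize(c(1, 2, 3))
  expect_equal(mean(z), 0)
  expect_equal(sd(z), 1)
  expect_equal(standardize(z), z)
  expect_error(standardize(rep(4, 10)), "constant")

  # reparameterisation oracle: a Poisson slope on the standardized
  # predictor equals the raw-predictor slope times SD(x)
  set.seed(12)
  x <- rnorm(80, 10, 3)
  y <- rpois(80, exp(1 + 0.1 * x))
  b_raw <- coef(glm(y ~ x, family = poisson()))[["x"]]
  b_std <- coef(glm(y ~ standardize(x), family = poisson()))[[2]]
  expect_equal(b_std, b_raw * sd(x), tolerance = 1e-8)
})

test_that("AIC selection keeps the simpler model unless dAIC > 2", {
  set.seed(21)
  x <- rnorm(400)
  z <- standardize(x)
  # pure linear truth: degree 1 wins
  y_lin <- rpois(400, exp(1 + 0.5 * z))
  f_lin <- select_polynomial(y_lin, z, poisson())
  expect_equal(f_lin$degree, 1)
  expect_named(f_lin$delta_aic, c("1", "2", "3"))
  # strong quadratic truth: degree 2 wins
  y_quad <- rpois(400, exp(1 + 0.3 * z + 0.5 * z^2))
  expect_equal(select_polynomial(y_quad, z, poisson())$degree, 2)
  # a higher degree within 2 AIC of the simpler model is never chosen,
  # by construction of the rule
  expect_true(all(f_lin$delta_aic[-1] > -2))
})

test_that("the abundance index recovers a known Poisson slope", {
  set.seed(33)
  rate <- rlnorm(50, 5, 0.6)
  z <- standardize(rate)
  aons <- rpois(50, exp(3 + 0.5 * z))
  fit <- fit_abundance_index(aons, rate, "adult_purr")
  expect_equal(fit$family, "poisson_log")
  expect_true(fit$ci_low < 0.5 && fit$ci_high > 0.5)
  expect_true(fit$significant)
  expect_equal(fit$n, 50)
  expect_error(fit_abundance_index(aons + 0.5, rate, "adult_purr"),
               "whole counts")
  expect_error(fit_abundance_index(c(1, 2, 3), c(1, 2, 3), "adult_purr"),
               "4 plots")
})

test_that("breeding-success models fit binomial responses and flag separation", {
  set.seed(44)
  n <- 12
  z <- rnorm(n)
  p <- plogis(1 + 0.8 * scale(z)[, 1])
  att <- rep(20, n)
  succ <- rbinom(n, att, p)
  fit <- fit_breeding_success(succ, att - succ, z)
  expect_s3_class(fit, "model_fit")
  expect_false(fit$separation)
  expect_gt(fit$estimate, 0)
  expect_true(fit$ci_low <= fit$estimate & fit$estimate <= fit$ci_high)

  # perfectly separable data triggers the shrinkage refit
  sep_succ <- c(0, 0, 0, 10, 10, 10)
  sep_fail <- 10 - sep_succ
  expect_warning(
    fit_sep <- fit_breeding_success(sep_succ, sep_fail, 1:6,
                                    degrees = 1),
    "separation")
  expect_true(fit_sep$separation)
  expect_true(is.finite(fit_sep$estimate))

  expect_error(fit_breeding_success(c(0, 1), c(0, 1), c(1, 2)), "attempt")
})

test_that("the acoustic breeding-success ratio handles zero denominators", {
  expect_equal(acoustic_breeding_success(30, 60), 0.5)
  expect_equal(acoustic_breeding_success(0, 60), 0)
  expect_warning(r <- acoustic_breeding_success(c(10, 5), c(20, 0)),
                 "zero or missing")
  expect_equal(r, c(0.5, NA))
})

test_that("correlation reports r, df and a calibrated p-value", {
  x <- 1:10
  ct <- correlate(x, x)
  expect_equal(ct$r, 1)
  expect_equal(ct$df, 8)
  # null calibration: with n = 10 the two-sided 5% critical value is
  # |r| = 0.632; about 5% of independent draws exceed it
  set.seed(55)
  hits <- mean(vapply(1:1000, function(i) {
    abs(correlate(rnorm(10), rnorm(10))$r) > 0.632
  }, logical(1)))
  expect_gt(hits, 0.03)
  expect_lt(hits, 0.075)
  expect_error(correlate(1:2, 1:2), "3 complete pairs")
  expect_error(correlate(rep(1, 5), 1:5), "constant")
})
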