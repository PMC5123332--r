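test_that("mean RR is the geometric mean of the per-iteration RRs", {
  expect_equal(mean_rr(rep(log(1.05), 10)), 1.05)
  expect_equal(mean_rr(c(log(1.02), log(1.08))), sqrt(1.02 * 1.08))
  expect_equal(mean_rr(rep(0, 5)), 1)
  expect_error(mean_rr(numeric(0)), "empty")
})

test_that("percent attenuation follows its defining ratio", {
  expect_equal(percent_attenuation(1.05, 1.05), 0)
  expect_equal(percent_attenuation(1.05, 1.00), 100)
  expect_equal(percent_attenuation(1.05, 1.0345), 31, tolerance = 1e-6)
  expect_lt(percent_attenuation(1.05, 1.06), 0)    # bias away from the null
  expect_error(percent_attenuation(1, 1.0), "undefined")
  # invariant to N: depends only on the mean log RR
  b <- rnorm(50, log(1.03), 0.01)
  expect_equal(percent_attenuation(1.05, mean_rr(b)),
               percent_attenuation(1.05, mean_rr(rep(mean(b), 7))))
})

test_that("RMSE and the RMSE ratio match their definitions", {
  expect_equal(rmse(rep(log(1.05), 8), 1.05), 0)
  expect_equal(rmse(log(1.05) + c(0.1, -0.1), 1.05), 0.1)
  set.seed(41)
  draws <- rnorm(1e5, log(1.05), 0.07)   # unbiased: RMSE -> sd
  expect_equal(rmse(draws, 1.05), 0.07, tolerance = 0.01)
  expect_equal(rmse_ratio(0.4, 0.2), 2)
  expect_error(rmse_ratio(0.4, 0), "rmse_true")
})

test_that("power / type I error and its binomial SE follow the defining formulas", {
  z3 <- power_type1(rep(3, 10), rep(1, 10))
  expect_equal(z3$proportion, 1)
  expect_equal(z3$se, 0)
  expect_equal(power_type1(rep(0, 10), rep(1, 10))$proportion, 0)

  half <- power_type1(c(rep(3, 500), rep(0, 500)), rep(1, 1000))
  expect_equal(half$proportion, 0.5)
  expect_equal(half$se, sqrt(0.25 / 1000), tolerance = 1e-10)

  # one-sided rule counts only positive exceedances
  expect_equal(power_type1(c(-3, 3), c(1, 1), two_sided = FALSE)$proportion,
               0.5)
  expect_equal(power_type1(c(-3, 3), c(1, 1), two_sided = TRUE)$proportion, 1)
  expect_error(power_type1(c(1, 2), c(1, 0)), "standard errors")
  expect_error(power_type1(numeric(0), numeric(0)), "non-empty")
})

test_that("CI coverage matches normal theory", {
  expect_equal(ci_coverage(rep(log(1.05), 9), rep(0.1, 9), log(1.05)), 1)
  expect_equal(ci_coverage(rep(1, 9), rep(0.1, 9), 0), 0)  # 10 sigma off
  set.seed(43)
  b <- rnorm(1e5, 0.2, 0.05)
  expect_equal(ci_coverage(b, rep(0.05, 1e5), 0.2), 0.95, tolerance = 0.005)
})

test_that("copollutant streams are compared with a Welch two-sided t-test", {
  x <- rnorm(100)
  same <- compare_copollutants(x, x)
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)

  set.seed(47)
  sep <- compare_copollutants(rnorm(1000, 0), rnorm(1000, 1))
  expect_lt(sep$p_value, 1e-3)
  expect_error(compare_copollutants(1, rnorm(5)), "length >= 2")

  # null calibration: rejection rate ~ alpha
  set.seed(49)
  rej <- mean(replicate(400, {
    compare_copollutants(rnorm(40), rnorm(40))$p_value < 0.05
  }))
  expect_lt(abs(rej - 0.05), 2.5 * sqrt(0.05 * 0.95 / 400))
})

test_that("classical error attenuates the RR by the reliability ratio", {
  # analytic oracle: for jointly normal (x, w = x + u) and log-linear mean,
  # the slope in w is exactly lambda * beta with lambda = Var(x)/Var(w)
  n <- 4000
  design <- intercept_design(n)
  B <- c("(Intercept)" = log(3))
  beta <- log(1.3)
  run_one <- function(var_u, seed) {
    set.seed(seed)
    x <- rnorm(n, 0, 1)
    w <- x + rnorm(n, 0, sqrt(var_u))
    mu <- exp(log(3) + beta * x)
    y <- rpois(n, mu)
    co <- rnorm(n)  # independent second pollutant, null effect
    noisy <- fit_copollutant_model(design, y, w, co)
    noisy$beta1
  }
  var_u <- 2 / 3   # reliability ratio lambda = 0.6
  betas <- sapply(1:40, function(s) run_one(var_u, 1000 + s))
  atten <- 1 - mean(betas) / beta
  expect_equal(atten, 1 - 0.6, tolerance = 0.12)

  # attenuation is monotone non-decreasing in the injected error variance
  ladder <- sapply(c(0.25, 1, 3), function(v) {
    mean(sapply(1:15, function(s) run_one(v, 2000 + 100 * v + s)))
  })
  expect_true(all(diff(ladder) < 0))   # estimates shrink toward the null
})

test_that("scenario summaries assemble the full metrics row", {
  pl <- small_pipeline()
  res <- run_scenario(pl$cfg, pl$panel, pl$calib, pl$B, "CO", "NOx",
                      design = pl$design, n_iterations = 5L)
  m <- summarize_scenario(res)
  expect_equal(nrow(m), 1L)
  expect_equal(m$pol1, "CO")
  expect_equal(m$n_iterations, 5L)
  expect_gte(m$main_true_rmse, 0)
  expect_true(m$co_true_power_or_type1 >= 0 && m$co_true_power_or_type1 <= 1)
  expect_true(m$main_true_coverage95 >= 0 && m$main_true_coverage95 <= 1)
  expect_equal(m$main_rmse_ratio, m$main_noisy_rmse / m$main_true_rmse)
  expect_equal(m$pct_attenuation,
               percent_attenuation(1.05, m$main_noisy_mean_rr))
  # the reported Monte Carlo SE is sd / sqrt(N)
  expect_equal(m$main_true_se_mean_log_rr,
               m$main_true_sd_log_rr / sqrt(5))
})
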