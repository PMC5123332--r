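test_that("zero-noise calibration reproduces the configured line exactly", {
  cfg <- two_pollutant_config(resid_sd = c(0, 0),
                              theta1_mean = c(1, 2), theta2_mean = c(2, 0.5))
  panel <- generate_exposure_panel(cfg, seed = 11L)
  wide <- tidyr::pivot_wider(panel, names_from = "metric",
                             values_from = "value")
  th1 <- unname(c(A = 1, B = 2)[wide$pollutant])
  th2 <- unname(c(A = 2, B = 0.5)[wide$pollutant])
  expect_equal(wide$AQ, th1 + th2 * wide$CS, tolerance = 1e-12)
  expect_equal(wide$PE, th1 + th2 * wide$AQ, tolerance = 1e-12)
})

test_that("identity calibration makes all three metrics coincide", {
  cfg <- two_pollutant_config(resid_sd = c(0, 0))
  wide <- tidyr::pivot_wider(generate_exposure_panel(cfg, seed = 2L),
                             names_from = "metric", values_from = "value")
  expect_equal(wide$AQ, wide$CS)
  expect_equal(wide$PE, wide$CS)
})

test_that("central-site values are shared across ZIP codes", {
  panel <- suppressMessages(generate_exposure_panel(small_config()))
  cs <- panel[panel$metric == "CS", ]
  spread <- dplyr::summarise(
    dplyr::group_by(cs, .data$day, .data$pollutant),
    d = max(.data$value) - min(.data$value), .groups = "drop")
  expect_equal(max(spread$d), 0)
  # exactly one value per (zip, day, pollutant, metric)
  expect_equal(anyDuplicated(panel[, c("zip_id", "day", "pollutant",
                                       "metric")]), 0L)
})

test_that("generated residual correlation matches the configured value", {
  # long panel, correlation estimated from per-zip OLS residuals
  cfg <- two_pollutant_config(n_days = 5000L, err_rho = 0.6,
                              resid_sd = c(1, 1), conc_rho = 0.3)
  panel <- generate_exposure_panel(cfg, seed = 31L)
  wide <- tidyr::pivot_wider(panel[panel$zip_id == "Z01", ],
                             names_from = "metric", values_from = "value")
  res <- sapply(c("A", "B"), function(p) {
    sub <- wide[wide$pollutant == p, ]
    resid(lm(AQ ~ CS, data = sub))
  })
  expect_equal(cor(res[, "A"], res[, "B"]), 0.6, tolerance = 0.05 / 0.6)
  # sample covariance of the errors converges to the configured covariance
  expect_equal(unname(apply(res, 2, sd)), c(1, 1), tolerance = 0.05)
})

test_that("panels and covariates are reproducible from the seed", {
  cfg <- small_config()
  p1 <- suppressMessages(generate_exposure_panel(cfg, seed = 9L))
  p2 <- suppressMessages(generate_exposure_panel(cfg, seed = 9L))
  p3 <- suppressMessages(generate_exposure_panel(cfg, seed = 10L))
  expect_identical(p1, p2)
  expect_false(isTRUE(all.equal(p1$value, p3$value)))

  c1 <- generate_covariates(cfg, seed = 9L)
  c2 <- generate_covariates(cfg, seed = 9L)
  c3 <- generate_covariates(cfg, seed = 10L)
  expect_identical(c1, c2)
  expect_false(identical(c1, c3))
})

test_that("covariate calendar arithmetic and hospital windows are correct", {
  # 14 days starting on a Monday cycle Mon..Sun twice
  cfg <- small_config(start_date = "1999-01-04", n_days = 70L)
  cov <- generate_covariates(cfg)
  one_zip <- cov[cov$zip_id == "Z01", ][1:14, ]
  expect_equal(as.character(one_zip$day_of_week),
               rep(c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun"), 2))
  expect_true(all(cov$max_temp >= cov$min_temp))
  expect_true(all(is.finite(cov$max_temp) & is.finite(cov$min_temp)))

  # each hospital active over one contiguous window covering >= 50% of days
  hosp <- as.matrix(cov[cov$zip_id == "Z01", grep("^hosp_", names(cov))])
  for (h in seq_len(ncol(hosp))) {
    act <- which(hosp[, h] == 1L)
    expect_gte(length(act), cfg$n_days / 2)
    expect_equal(act, seq(min(act), max(act)))
  }
})

test_that("local pollutants carry larger spatial error variance than regional", {
  panel <- suppressMessages(generate_exposure_panel(default_scenario(),
                                                    seed = 1L))
  err <- compute_error_panel(panel)
  spa <- err[err$error_type == "spatial", ]
  # compare on the IQR-standardised concentration scale so units cancel
  cs <- panel[panel$metric == "CS", ]
  iqrs <- tapply(cs$value, cs$pollutant, IQR)
  v <- dplyr::summarise(dplyr::group_by(spa, .data$pollutant),
                        v = var(.data$delta / iqrs[.data$pollutant[1]]),
                        .groups = "drop")
  local <- c("CO", "NOx", "EC"); regional <- c("PM25", "SO4", "O3")
  expect_gt(min(v$v[v$pollutant %in% local]),
            max(v$v[v$pollutant %in% regional]))
})

test_that("baseline Poisson coefficients are recovered from simulated counts", {
  cfg <- small_config(baseline_rate = 60)   # high rate: tight asymptotics
  design <- suppressMessages(build_design_matrix(generate_covariates(cfg)))
  B_star <- default_baseline_coefficients(design, cfg$baseline_rate)
  set.seed(13)
  counts <- simulate_counts(design, B_star)
  B_hat <- fit_baseline_coefficients(design, counts)
  se <- attr(B_hat, "se")
  expect_true(all(abs(B_hat - B_star) <= 3 * se))
})

test_that("degenerate count inputs are rejected with closed-form checks", {
  design <- intercept_design(50)
  counts <- tibble::tibble(zip_id = design$zip_id, day = design$day,
                           count = rep(4L, 50))
  B <- fit_baseline_coefficients(design, counts)
  expect_equal(unname(B["(Intercept)"]), log(4), tolerance = 1e-8)

  counts$count <- 0L
  expect_error(fit_baseline_coefficients(design, counts), "all counts are zero")
  counts$count <- c(-1L, rep(1L, 49))
  expect_error(fit_baseline_coefficients(design, counts), "nonnegative")
})
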