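test_that("error deltas follow their defining arithmetic", {
  panel <- identity_panel(n_days = 12L)
  one <- panel$zip_id == "Z01" & panel$day == 1L & panel$pollutant == "A"
  panel$value[one & panel$metric == "CS"] <- 3
  panel$value[one & panel$metric == "AQ"] <- 5
  panel$value[one & panel$metric == "PE"] <- 4

  err <- compute_error_panel(panel)
  cell <- err[err$zip_id == "Z01" & err$day == 1L & err$pollutant == "A", ]
  expect_equal(cell$delta[cell$error_type == "spatial"], 2)
  expect_equal(cell$delta[cell$error_type == "population"], -1)
  expect_equal(cell$delta[cell$error_type == "total"], 1)

  # identity panel elsewhere: spatial error identically zero
  rest <- err[!(err$zip_id == "Z01" & err$day == 1L & err$pollutant == "A"), ]
  expect_true(all(rest$delta == 0))
})

test_that("spatial + population = total on any generated panel", {
  panel <- suppressMessages(generate_exposure_panel(small_config()))
  err <- compute_error_panel(panel)
  wide <- tidyr::pivot_wider(err, names_from = "error_type",
                             values_from = "delta")
  expect_lt(max(abs(wide$spatial + wide$population - wide$total)), 1e-9)
})

test_that("a missing metric is reported with the incomplete tuple", {
  panel <- identity_panel(n_days = 12L)
  panel <- panel[!(panel$zip_id == "Z02" & panel$day == 3L &
                     panel$pollutant == "B" & panel$metric == "PE"), ]
  expect_error(compute_error_panel(panel), "PE.*Z02.*day 3.*B")
  expect_error(fit_calibrations(panel, "population"), "PE.*Z02")
})

test_that("a noiseless linear relation is calibrated exactly", {
  panel <- identity_panel(n_days = 40L)
  # AQ = 2*CS + 1 exactly
  panel$value[panel$metric == "AQ"] <- 2 * panel$value[panel$metric == "CS"] + 1
  calib <- fit_calibrations(panel, "spatial")
  expect_equal(calib$theta$theta1, rep(1, nrow(calib$theta)), tolerance = 1e-8)
  expect_equal(calib$theta$theta2, rep(2, nrow(calib$theta)), tolerance = 1e-8)
  expect_lt(max(abs(calib$theta[, c("cov11", "cov12", "cov22", "resid_var")])),
            1e-12)
  expect_lt(max(abs(calib$resid_cov$cov_ab)), 1e-12)
})

test_that("calibration on an identity panel gives theta = (0, 1) everywhere", {
  calib <- fit_calibrations(identity_panel(n_days = 25L), "total")
  expect_equal(calib$theta$theta1, rep(0, nrow(calib$theta)), tolerance = 1e-10)
  expect_equal(calib$theta$theta2, rep(1, nrow(calib$theta)), tolerance = 1e-10)
})

test_that("calibration recovers the generator's parameters at large n", {
  cfg <- two_pollutant_config(n_days = 5000L, err_rho = 0.5,
                              resid_sd = c(1.5, 0.8),
                              theta1_mean = c(1, -2), theta2_mean = c(1.3, 0.7))
  panel <- generate_exposure_panel(cfg, seed = 17L)
  calib <- fit_calibrations(panel, "spatial")
  th <- calib$theta
  truth1 <- c(A = 1, B = -2)[th$pollutant]
  truth2 <- c(A = 1.3, B = 0.7)[th$pollutant]
  expect_true(all(abs(th$theta1 - truth1) <= 3 * sqrt(th$cov11)))
  expect_true(all(abs(th$theta2 - truth2) <= 3 * sqrt(th$cov22)))

  truth_var <- c(A = 1.5^2, B = 0.8^2)[th$pollutant]
  expect_equal(th$resid_var, unname(truth_var), tolerance = 0.10)
  truth_cov <- 0.5 * 1.5 * 0.8
  expect_equal(calib$resid_cov$cov_ab,
               rep(truth_cov, nrow(calib$resid_cov)), tolerance = 0.10)

  # diagonal of the pair covariance equals each single fit's residual variance
  m <- copolsim:::pair_resid_cov(calib, "Z01", "A", "B")
  expect_equal(diag(m), th$resid_var[th$zip_id == "Z01"][1:2])
})

test_that("independent error streams give near-zero residual covariance", {
  cfg <- two_pollutant_config(n_days = 5000L, err_rho = 0,
                              resid_sd = c(1, 2))
  panel <- generate_exposure_panel(cfg, seed = 19L)
  calib <- fit_calibrations(panel, "spatial")
  geo_mean_var <- sqrt(1^2 * 2^2)
  expect_true(all(abs(calib$resid_cov$cov_ab) <= 0.05 * geo_mean_var * 2))
})

test_that("noiseless reconstruction reproduces the refined metric per ZIP", {
  cfg <- two_pollutant_config(n_days = 200L, err_rho = 0.3,
                              resid_sd = c(0.8, 0.8),
                              theta1_mean = c(0.5, 1), theta2_mean = c(1.1, 0.9))
  panel <- generate_exposure_panel(cfg, seed = 23L)
  calib <- fit_calibrations(panel, "spatial")
  wide <- tidyr::pivot_wider(panel, names_from = "metric",
                             values_from = "value")
  joined <- dplyr::left_join(wide, calib$theta,
                             by = c("zip_id", "pollutant"))
  resid <- joined$AQ - (joined$theta1 + joined$theta2 * joined$CS)
  per_zip_mean <- tapply(resid, paste(joined$zip_id, joined$pollutant), mean)
  expect_lt(max(abs(per_zip_mean)), 1e-10)
})

test_that("constant predictors and short series are rejected", {
  panel <- identity_panel(n_days = 20L)
  panel$value[panel$metric == "CS" & panel$pollutant == "A"] <- 7
  expect_error(fit_calibrations(panel, "spatial"), "constant predictor")
  expect_error(fit_calibrations(identity_panel(n_days = 5L), "spatial"),
               "fewer than 10 days")
})

test_that("calibration sets serialize to CSV for audit", {
  calib <- fit_calibrations(identity_panel(n_days = 30L), "spatial")
  stem <- file.path(withr::local_tempdir(), "calib")
  paths <- write_calibrations(calib, stem)
  expect_true(all(file.exists(paths)))
  back <- readr::read_csv(paths[1], show_col_types = FALSE)
  expect_equal(nrow(back), nrow(calib$theta))
})
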