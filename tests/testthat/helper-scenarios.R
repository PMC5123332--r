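# Shared fixtures, built in code.  Heavy objects are memoised across test
# files within one run.

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .cache)) {
    assign(key, force(expr), envir = .cache)
  }
  get(key, envir = .cache)
}

# small desk config for structural tests
small_config <- function(...) {
  args <- modifyList(
    list(n_zips = 3L, n_days = 120L, n_hospitals = 2L,
         baseline_rate = 5, n_iterations = 3L, seed = 42L),
    list(...)
  )
  do.call(default_scenario, args)
}

# minimal two-pollutant scenario with fully controllable calibration
two_pollutant_config <- function(n_zips = 2L, n_days = 120L,
                                 err_rho = 0, conc_rho = 0.3,
                                 resid_sd = c(1, 1),
                                 theta1_mean = c(0, 0), theta1_sd = c(0, 0),
                                 theta2_mean = c(1, 1), theta2_sd = c(0, 0),
                                 seed = 7L, ...) {
  pols <- tibble::tibble(pollutant = c("A", "B"),
                         class = c("local", "regional"))
  cal <- dplyr::bind_rows(lapply(c("AQ", "PE"), function(lv) {
    tibble::tibble(pollutant = pols$pollutant, level = lv,
                   theta1_mean = theta1_mean, theta1_sd = theta1_sd,
                   theta2_mean = theta2_mean, theta2_sd = theta2_sd,
                   resid_sd = resid_sd)
  }))
  cmat <- function(rho) {
    matrix(c(1, rho, rho, 1), 2, 2,
           dimnames = list(pols$pollutant, pols$pollutant))
  }
  scenario_config(
    n_zips = n_zips, n_days = n_days, pollutants = pols, n_hospitals = 1L,
    calibration_params = cal, error_correlation = cmat(err_rho),
    concentration_params = tibble::tibble(
      pollutant = pols$pollutant, level = c(10, 20),
      amplitude = c(2, 3), phi = 0.4, innov_sd = c(2, 3)),
    concentration_correlation = cmat(conc_rho),
    baseline_rate = 5, seed = seed, ...
  )
}

# hand-built calibration set with identical structure for every zip
manual_calibration <- function(zips, pol1, pol2, theta1 = 0, theta2 = 1,
                               theta_cov = matrix(0, 2, 2),
                               var1 = 0, var2 = 0, cov12 = 0,
                               error_type = "spatial") {
  theta <- dplyr::bind_rows(lapply(zips, function(z) {
    tibble::tibble(zip_id = z, pollutant = c(pol1, pol2),
                   error_type = error_type,
                   theta1 = theta1, theta2 = theta2,
                   cov11 = theta_cov[1, 1], cov12 = theta_cov[1, 2],
                   cov22 = theta_cov[2, 2],
                   resid_var = c(var1, var2), n_days = 100L)
  }))
  rc <- dplyr::bind_rows(lapply(zips, function(z) {
    tibble::tibble(zip_id = z, pollutant_a = pol1, pollutant_b = pol2,
                   error_type = error_type, cov_ab = cov12)
  }))
  structure(list(theta = theta, resid_cov = rc, error_type = error_type),
            class = "calibration_set")
}

# tiny long-format panel where all three metrics equal `values`
identity_panel <- function(zips = c("Z01", "Z02"), n_days = 30L,
                           pollutants = c("A", "B"), seed = 5L) {
  set.seed(seed)
  grid <- tidyr::expand_grid(zip_id = zips, day = seq_len(n_days),
                             pollutant = pollutants)
  grid$value <- rnorm(nrow(grid), 10, 2)
  out <- dplyr::bind_rows(
    dplyr::mutate(grid, metric = "CS"),
    dplyr::mutate(grid, metric = "AQ"),
    dplyr::mutate(grid, metric = "PE")
  )
  out$date <- as.Date("1999-01-01") + out$day - 1L
  out
}

# intercept-only design over n cells (single zip, n days)
intercept_design <- function(n) {
  structure(
    list(X = matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")),
         zip_id = rep("Z01", n), day = seq_len(n),
         blocks = list(intercept = "(Intercept)"), dropped = character(0)),
    class = "health_design"
  )
}

# memoised small-scale pipeline shared by engine tests
small_pipeline <- function() {
  memo("small_pipeline", {
    cfg <- small_config()
    panel <- suppressMessages(generate_exposure_panel(cfg))
    design <- suppressMessages(build_design_matrix(generate_covariates(cfg)))
    B0 <- default_baseline_coefficients(design, cfg$baseline_rate)
    set.seed(cfg$seed + 2L)
    counts <- simulate_counts(design, B0)
    B <- fit_baseline_coefficients(design, counts)
    list(cfg = cfg, panel = panel, design = design, B = B,
         calib = fit_calibrations(panel, "spatial"))
  })
}

# memoised default-scale Monte Carlo run backing the acceptance tests: one
# N = 500 scenario; the first 200 iterations stand in for an N = 200 run
# (iterations are iid), the full 500 back the null-calibration and coverage
# checks, which the spec allows at N up to 1000
default_run <- function() {
  memo("default_run", {
    cfg <- default_scenario()
    panel <- suppressMessages(generate_exposure_panel(cfg))
    design <- suppressMessages(build_design_matrix(generate_covariates(cfg)))
    B0 <- default_baseline_coefficients(design, cfg$baseline_rate)
    set.seed(cfg$seed + 2L)
    B <- fit_baseline_coefficients(design, simulate_counts(design, B0))
    calib <- fit_calibrations(panel, "spatial")
    res <- run_scenario(cfg, panel, calib, B, "CO", "O3", design = design,
                        n_iterations = 500L)
    list(cfg = cfg, result = res, metrics = summarize_scenario(res))
  })
}
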