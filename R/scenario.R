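#' Scenario configuration for a copollutant measurement-error simulation
#'
#' A scenario bundles everything needed to generate a synthetic exposure
#' panel and run the Monte Carlo experiment: the panel dimensions, the
#' pollutants and their spatial class, the calibration (measurement-error)
#' process linking the three exposure metrics, the daily concentration
#' process, the health-outcome baseline, and the assumed relative risks.
#'
#' The three exposure metrics are: `CS`, a central-site measurement shared by
#' all ZIP codes on a day; `AQ`, a spatially refined ambient estimate per ZIP
#' code; and `PE`, a population exposure estimate additionally reflecting
#' human activity and infiltration.  `AQ` is generated from `CS`, and `PE`
#' from `AQ`, by ZIP-specific linear calibrations
#' `refined = theta1 + theta2 * unrefined + eps` with residuals `eps` drawn
#' jointly across pollutants with a configurable correlation.
#'
#' @param n_zips Number of ZIP-code areas (>= 2).
#' @param n_days Number of study days (>= 60; the monthly-knot spline needs
#'   at least two months).
#' @param start_date First study day (`Date` or ISO-8601 string).
#' @param pollutants Data frame with columns `pollutant` (label) and `class`
#'   (`"local"` or `"regional"`).
#' @param n_hospitals Number of hospitals contributing counts.
#' @param calibration_params Data frame with one row per pollutant x level
#'   (`level` in `"AQ"`, `"PE"`): columns `pollutant`, `level`, `theta1_mean`,
#'   `theta1_sd`, `theta2_mean`, `theta2_sd` (across-ZIP spread of the
#'   additive and multiplicative bias) and `resid_sd` (residual standard
#'   deviation, concentration units).
#' @param error_correlation Between-pollutant correlation matrix of the
#'   calibration residuals (applies at both the AQ and PE stages).
#' @param concentration_params Data frame with one row per pollutant:
#'   `level` (annual mean), `amplitude` (seasonal amplitude), `phi`
#'   (day-to-day AR(1) coefficient in [0, 1)), `innov_sd` (AR(1) innovation
#'   standard deviation).
#' @param concentration_correlation Between-pollutant correlation matrix of
#'   the daily concentration innovations.
#' @param baseline_rate Expected ED counts per ZIP-day.
#' @param rr_main Assumed relative risk per IQR for the main pollutant.
#' @param rr_co Assumed relative risk per IQR for the copollutant.
#' @param n_iterations Monte Carlo iteration count N.
#' @param seed Master integer seed.
#'
#' @return An object of class `scenario_config` (a named list).
#' @seealso [default_scenario()], [read_scenario()], [write_scenario()]
#' @export
scenario_config <- function(n_zips,
                            n_days,
                            start_date = "1999-01-01",
                            pollutants,
                            n_hospitals,
                            calibration_params,
                            error_correlation,
                            concentration_params,
                            concentration_correlation,
                            baseline_rate = 2,
                            rr_main = 1.05,
                            rr_co = 1,
                            n_iterations = 200,
                            seed = 1L) {
  cfg <- structure(
    list(
      n_zips = as.integer(n_zips),
      n_days = as.integer(n_days),
      start_date = as.Date(start_date),
      pollutants = tibble::as_tibble(pollutants),
      n_hospitals = as.integer(n_hospitals),
      calibration_params = tibble::as_tibble(calibration_params),
      error_correlation = as.matrix(error_correlation),
      concentration_params = tibble::as_tibble(concentration_params),
      concentration_correlation = as.matrix(concentration_correlation),
      baseline_rate = baseline_rate,
      rr_main = rr_main,
      rr_co = rr_co,
      n_iterations = as.integer(n_iterations),
      seed = as.integer(seed)
    ),
    class = "scenario_config"
  )
  validate_scenario(cfg)
}

#' Validate a scenario configuration
#'
#' Checks panel dimensions, relative risks, the completeness of the
#' calibration and concentration tables, and that both correlation matrices
#' are symmetric positive semi-definite with unit diagonal.
#'
#' @param cfg A `scenario_config`.
#' @return `cfg`, invisibly unchanged, or an error describing the first
#'   violated constraint (naming the offending matrix for PSD failures).
#' @export
validate_scenario <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  if (cfg$n_zips < 2L) stop("n_zips must be >= 2", call. = FALSE)
  if (cfg$n_days < 60L) stop("n_days must be >= 60", call. = FALSE)
  if (cfg$n_iterations < 1L) stop("n_iterations must be >= 1", call. = FALSE)
  if (cfg$n_hospitals < 1L) stop("n_hospitals must be >= 1", call. = FALSE)
  if (!(cfg$rr_main > 0)) stop("rr_main must be > 0", call. = FALSE)
  if (!(cfg$rr_co > 0)) stop("rr_co must be > 0", call. = FALSE)
  if (!(cfg$baseline_rate > 0)) stop("baseline_rate must be > 0", call. = FALSE)

  pols <- cfg$pollutants$pollutant
  if (anyDuplicated(pols)) stop("duplicate pollutant labels", call. = FALSE)
  if (!all(cfg$pollutants$class %in% c("local", "regional"))) {
    stop("pollutant class must be 'local' or 'regional'", call. = FALSE)
  }

  need <- expand.grid(pollutant = pols, level = c("AQ", "PE"),
                      stringsAsFactors = FALSE)
  have <- cfg$calibration_params[, c("pollutant", "level")]
  if (nrow(dplyr::anti_join(need, have, by = c("pollutant", "level"))) > 0) {
    stop("calibration_params must cover every pollutant at levels AQ and PE",
         call. = FALSE)
  }
  if (any(cfg$calibration_params$resid_sd < 0) ||
      any(cfg$calibration_params$theta1_sd < 0) ||
      any(cfg$calibration_params$theta2_sd < 0)) {
    stop("calibration standard deviations must be >= 0", call. = FALSE)
  }
  if (!setequal(cfg$concentration_params$pollutant, pols)) {
    stop("concentration_params must cover every pollutant", call. = FALSE)
  }
  if (any(cfg$concentration_params$phi < 0 | cfg$concentration_params$phi >= 1)) {
    stop("AR(1) coefficient phi must lie in [0, 1)", call. = FALSE)
  }

  check_correlation_matrix(cfg$error_correlation, pols, "error_correlation")
  check_correlation_matrix(cfg$concentration_correlation, pols,
                           "concentration_correlation")
  invisible(cfg)
}

# Symmetric, unit diagonal, PSD, rows/cols named by the pollutants.
check_correlation_matrix <- function(m, pollutants, name) {
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop(sprintf("%s must have pollutant row and column names", name),
         call. = FALSE)
  }
  if (!setequal(rownames(m), pollutants) || !setequal(colnames(m), pollutants)) {
    stop(sprintf("%s must be indexed by the configured pollutants", name),
         call. = FALSE)
  }
  m <- m[pollutants, pollutants, drop = FALSE]
  if (max(abs(m - t(m))) > 1e-8) {
    stop(sprintf("%s is not symmetric", name), call. = FALSE)
  }
  if (max(abs(diag(m) - 1)) > 1e-8) {
    stop(sprintf("%s must have unit diagonal", name), call. = FALSE)
  }
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop(sprintf("%s is not positive semi-definite (min eigenvalue %.3g)",
                 name, min(ev)), call. = FALSE)
  }
  invisible(m)
}

#' Default synthetic scenario
#'
#' The shipped desk-scale study conditions: 15 ZIP codes, 730 days starting
#' 1999-01-01, six hospitals, six pollutants in two spatial classes (local:
#' CO, NOx, EC with larger and more strongly correlated calibration
#' residuals; regional: PM2.5, SO4, O3 with smaller residuals), baseline
#' rate 2 counts per ZIP-day, RR 1.05 per IQR for the main pollutant and 1
#' for the copollutant, and 200 Monte Carlo iterations.
#'
#' @param ... Named fields overriding the defaults (passed to
#'   [scenario_config()]).
#' @return A `scenario_config`.
#' @export
default_scenario <- function(...) {
  pollutants <- tibble::tibble(
    pollutant = c("CO", "NOx", "EC", "PM25", "SO4", "O3"),
    class     = c("local", "local", "local", "regional", "regional", "regional")
  )

  # Daily mean process per pollutant, order-of-magnitude plausible for an
  # urban airshed (CO ppm; NOx, O3 ppb; EC, PM25, SO4 ug/m3).
  concentration_params <- tibble::tibble(
    pollutant = pollutants$pollutant,
    level     = c(0.6, 45, 1.5, 16, 4.5, 42),
    amplitude = c(0.08, 8, 0.25, 3, 1.2, 14),
    phi       = 0.5,
    innov_sd  = c(0.20, 15, 0.50, 4.3, 1.3, 10)
  )

  # Local pollutants: heterogeneous multiplicative bias across ZIPs and
  # large calibration residuals; regional: nearly shared calibration with
  # small residuals.  PE-stage residuals are larger than AQ-stage for the
  # local class (activity/infiltration adds error on top of space).
  calib <- function(level, t1m, t1s, t2m, t2s, rsd) {
    tibble::tibble(pollutant = pollutants$pollutant, level = level,
                   theta1_mean = t1m, theta1_sd = t1s,
                   theta2_mean = t2m, theta2_sd = t2s, resid_sd = rsd)
  }
  calibration_params <- dplyr::bind_rows(
    calib("AQ",
          t1m = c(0.05, 4, 0.15, 1.0, 0.3, 3),
          t1s = c(0.03, 2.5, 0.08, 0.5, 0.15, 1.5),
          t2m = c(0.9, 0.9, 0.9, 0.98, 0.98, 0.95),
          t2s = c(0.25, 0.25, 0.25, 0.06, 0.06, 0.08),
          rsd = c(0.30, 22, 0.75, 1.7, 0.55, 4.5)),
    calib("PE",
          t1m = c(0.02, 2, 0.05, 0.5, 0.15, 1.5),
          t1s = c(0.02, 1.5, 0.05, 0.3, 0.08, 1.0),
          t2m = c(0.95, 0.85, 0.9, 0.9, 0.92, 0.85),
          t2s = c(0.15, 0.20, 0.18, 0.05, 0.05, 0.08),
          rsd = c(0.12, 18, 0.60, 2.2, 0.70, 6.0))
  )

  blk <- function(within_local, within_regional, cross) {
    m <- matrix(cross, 6, 6, dimnames = list(pollutants$pollutant,
                                             pollutants$pollutant))
    m[1:3, 1:3] <- within_local
    m[4:6, 4:6] <- within_regional
    diag(m) <- 1
    m
  }
  error_correlation <- blk(0.6, 0.4, 0.2)
  concentration_correlation <- blk(0.7, 0.5, 0.3)
  # ozone is photochemical: weakly anti-correlated with fresh combustion
  for (p in c("CO", "NOx", "EC")) {
    concentration_correlation[p, "O3"] <- -0.2
    concentration_correlation["O3", p] <- -0.2
  }

  args <- modifyList(
    list(
      n_zips = 15L, n_days = 730L, start_date = "1999-01-01",
      pollutants = pollutants, n_hospitals = 6L,
      calibration_params = calibration_params,
      error_correlation = error_correlation,
      concentration_params = concentration_params,
      concentration_correlation = concentration_correlation,
      baseline_rate = 2, rr_main = 1.05, rr_co = 1,
      n_iterations = 200L, seed = 1L
    ),
    list(...)
  )
  do.call(scenario_config, args)
}

#' Read or write a scenario configuration as YAML
#'
#' The YAML layout mirrors the fields of [scenario_config()]; matrices are
#' stored with explicit pollutant row order.  Unknown top-level keys are
#' rejected so that typos fail loudly rather than silently falling back to
#' defaults.
#'
#' @param path File path.
#' @param cfg A `scenario_config` (for writing).
#' @return `read_scenario()` returns a validated `scenario_config`;
#'   `write_scenario()` returns `path` invisibly.
#' @export
read_scenario <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("n_zips", "n_days", "start_date", "pollutants", "n_hospitals",
             "calibration_params", "error_correlation",
             "concentration_params", "concentration_correlation",
             "baseline_rate", "rr_main", "rr_co", "n_iterations", "seed")
  extra <- setdiff(names(raw), known)
  if (length(extra) > 0) {
    stop("unknown scenario keys: ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  as_mat <- function(x) {
    pols <- names(x)
    m <- do.call(rbind, lapply(x, function(r) unlist(r)[pols]))
    dimnames(m) <- list(pols, pols)
    m
  }
  raw$pollutants <- dplyr::bind_rows(raw$pollutants)
  raw$calibration_params <- dplyr::bind_rows(raw$calibration_params)
  raw$concentration_params <- dplyr::bind_rows(raw$concentration_params)
  raw$error_correlation <- as_mat(raw$error_correlation)
  raw$concentration_correlation <- as_mat(raw$concentration_correlation)
  do.call(scenario_config, raw)
}

#' @rdname read_scenario
#' @export
write_scenario <- function(cfg, path) {
  stopifnot(inherits(cfg, "scenario_config"))
  mat_to_list <- function(m) {
    out <- lapply(seq_len(nrow(m)), function(i) as.list(m[i, ]))
    names(out) <- rownames(m)
    out
  }
  out <- list(
    n_zips = cfg$n_zips, n_days = cfg$n_days,
    start_date = format(cfg$start_date),
    pollutants = lapply(seq_len(nrow(cfg$pollutants)),
                        function(i) as.list(cfg$pollutants[i, ])),
    n_hospitals = cfg$n_hospitals,
    calibration_params = lapply(seq_len(nrow(cfg$calibration_params)),
                                function(i) as.list(cfg$calibration_params[i, ])),
    error_correlation = mat_to_list(cfg$error_correlation),
    concentration_params = lapply(seq_len(nrow(cfg$concentration_params)),
                                  function(i) as.list(cfg$concentration_params[i, ])),
    concentration_correlation = mat_to_list(cfg$concentration_correlation),
    baseline_rate = cfg$baseline_rate,
    rr_main = cfg$rr_main, rr_co = cfg$rr_co,
    n_iterations = cfg$n_iterations, seed = cfg$seed
  )
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("<scenario_config>\n")
  cat(sprintf("  %d ZIPs x %d days from %s; %d hospitals\n",
              x$n_zips, x$n_days, format(x$start_date), x$n_hospitals))
  cat(sprintf("  pollutants: %s\n",
              paste(sprintf("%s(%s)", x$pollutants$pollutant,
                            substr(x$pollutants$class, 1, 3)),
                    collapse = ", ")))
  cat(sprintf("  baseline_rate %.3g, RR main %.3f / co %.3f, N = %d, seed %d\n",
              x$baseline_rate, x$rr_main, x$rr_co, x$n_iterations, x$seed))
  invisible(x)
}
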