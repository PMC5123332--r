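#' Generate a synthetic multi-pollutant exposure panel
#'
#' Builds the three exposure metrics for every ZIP code, day and pollutant.
#' The central-site series (`CS`) is shared across ZIP codes: for each
#' pollutant it is a seasonal sinusoid plus an AR(1) deviation whose
#' innovations are drawn jointly across pollutants with the configured
#' concentration correlation.  The spatially refined metric (`AQ`) is then
#' generated per ZIP as `theta1 + theta2 * CS + eps`, with the ZIP-specific
#' calibration coefficients drawn from the configured across-ZIP
#' distributions and the residuals `eps` drawn jointly across pollutants
#' with the configured error correlation.  The population metric (`PE`) is
#' generated from `AQ` by the same mechanism with the PE-level parameters.
#'
#' Negative concentrations are retained rather than truncated, so that the
#' configured covariance structure holds exactly; a message reports how many
#' were generated.
#'
#' @param config A [scenario_config()].
#' @param seed Integer seed; the panel is bit-reproducible given the seed.
#' @return A tibble in long format with columns `zip_id`, `day` (1-based
#'   index), `date`, `pollutant`, `metric` (`"CS"`, `"AQ"`, `"PE"`) and
#'   `value` (concentration, pollutant-native units) — one row per
#'   (zip, day, pollutant, metric).
#' @export
generate_exposure_panel <- function(config, seed = config$seed) {
  validate_scenario(config)
  set.seed(seed)

  pols <- config$pollutants$pollutant
  np <- length(pols)
  nd <- config$n_days
  nz <- config$n_zips
  dates <- config$start_date + (seq_len(nd) - 1L)

  cs <- simulate_cs_series(config)                    # nd x np matrix

  aq <- array(NA_real_, dim = c(nz, nd, np),
              dimnames = list(NULL, NULL, pols))
  pe <- aq
  for (k in seq_len(nz)) {
    aq[k, , ] <- apply_calibration_stage(cs, config, level = "AQ")
    pe[k, , ] <- apply_calibration_stage(aq[k, , ], config, level = "PE")
  }

  n_neg <- sum(cs < 0) * nz + sum(aq < 0) + sum(pe < 0)
  if (n_neg > 0) {
    message(sprintf("generate_exposure_panel: %d negative concentration values retained", n_neg))
  }

  zip_ids <- sprintf("Z%02d", seq_len(nz))
  grid <- tidyr::expand_grid(zip_id = zip_ids, day = seq_len(nd),
                             pollutant = pols)
  ki <- match(grid$zip_id, zip_ids)
  pi <- match(grid$pollutant, pols)
  idx <- cbind(ki, grid$day, pi)
  panel <- dplyr::bind_rows(
    dplyr::mutate(grid, metric = "CS", value = cs[cbind(grid$day, pi)]),
    dplyr::mutate(grid, metric = "AQ", value = aq[idx]),
    dplyr::mutate(grid, metric = "PE", value = pe[idx])
  )
  panel$date <- dates[panel$day]
  dplyr::arrange(
    panel[, c("zip_id", "day", "date", "pollutant", "metric", "value")],
    .data$zip_id, .data$day, .data$pollutant, .data$metric
  )
}

# Daily central-site concentrations: seasonal mean + AR(1) deviations with
# cross-pollutant correlated innovations.  Returns an n_days x n_pollutants
# matrix.  Consumes the current RNG stream.
simulate_cs_series <- function(config) {
  cp <- config$concentration_params
  pols <- config$pollutants$pollutant
  cp <- cp[match(pols, cp$pollutant), ]
  np <- length(pols)
  nd <- config$n_days

  corr <- config$concentration_correlation[pols, pols]
  sigma <- diag(cp$innov_sd, np) %*% corr %*% diag(cp$innov_sd, np)
  innov <- MASS::mvrnorm(nd, mu = rep(0, np), Sigma = sigma)
  innov <- matrix(innov, nrow = nd)

  z <- matrix(0, nd, np)
  # start the AR(1) at its stationary distribution
  z[1, ] <- innov[1, ] / sqrt(1 - cp$phi^2)
  for (t in 2:nd) z[t, ] <- cp$phi * z[t - 1, ] + innov[t, ]

  doy <- as.integer(format(config$start_date + (seq_len(nd) - 1L), "%j"))
  seasonal <- outer(cos(2 * pi * (doy - 15) / 365.25), cp$amplitude)
  out <- sweep(seasonal + z, 2, cp$level, "+")
  colnames(out) <- pols
  out
}

# One calibration stage (AQ from CS, or PE from AQ) for a single ZIP code:
# draws (theta1, theta2) per pollutant from the configured across-ZIP
# distributions, then adds residuals correlated across pollutants.
# `unrefined` is an n_days x n_pollutants matrix; returns same shape.
apply_calibration_stage <- function(unrefined, config, level) {
  pols <- config$pollutants$pollutant
  np <- length(pols)
  nd <- nrow(unrefined)
  cal <- dplyr::filter(config$calibration_params, .data$level == !!level)
  cal <- cal[match(pols, cal$pollutant), ]

  theta1 <- rnorm(np, cal$theta1_mean, cal$theta1_sd)
  theta2 <- rnorm(np, cal$theta2_mean, cal$theta2_sd)

  corr <- config$error_correlation[pols, pols]
  sigma <- diag(cal$resid_sd, np) %*% corr %*% diag(cal$resid_sd, np)
  eps <- if (all(cal$resid_sd == 0)) {
    matrix(0, nd, np)
  } else {
    matrix(MASS::mvrnorm(nd, mu = rep(0, np), Sigma = sigma), nrow = nd)
  }

  refined <- sweep(sweep(unrefined, 2, theta2, "*"), 2, theta1, "+") + eps
  colnames(refined) <- pols
  refined
}

#' Read or write an exposure panel as CSV
#'
#' Columns: `zip_id`, `date` (ISO-8601), `pollutant`, `metric`, `value`.
#' The 1-based `day` index is reconstructed from the date range on read.
#'
#' @param panel An exposure panel tibble.
#' @param path File path.
#' @return `read_exposure_panel()` returns the panel tibble;
#'   `write_exposure_panel()` returns `path` invisibly.
#' @export
write_exposure_panel <- function(panel, path) {
  readr::write_csv(panel[, c("zip_id", "date", "pollutant", "metric", "value")],
                   path)
  invisible(path)
}

#' @rdname write_exposure_panel
#' @export
read_exposure_panel <- function(path) {
  panel <- readr::read_csv(path, show_col_types = FALSE,
                           col_types = readr::cols(
                             zip_id = "c", date = readr::col_date(),
                             pollutant = "c", metric = "c", value = "d"))
  panel$day <- as.integer(panel$date - min(panel$date)) + 1L
  panel[, c("zip_id", "day", "date", "pollutant", "metric", "value")]
}
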