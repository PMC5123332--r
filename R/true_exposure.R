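#' Simulate the "true" exposure pair for one Monte Carlo iteration
#'
#' Reverses the estimated measurement-error process to simulate exposure
#' without error for two pollutants.  For each ZIP code, one realisation of
#' the calibration coefficients `(theta1, theta2)` per pollutant is drawn
#' from their asymptotic bivariate normal distribution (independently for
#' the two pollutants, held constant across days within the iteration);
#' then, for each day, a joint residual for the two pollutants is drawn
#' from a bivariate normal with the ZIP-specific empirical residual
#' covariance, and the true value is `theta1 + theta2 * unrefined + eps`,
#' where the unrefined predictor is `CS` for spatial/total error and `AQ`
#' for population error.  Because residual variance is added on top of the
#' fitted line, the simulated true exposure is more variable than the
#' unrefined, error-prone exposure it is built from.
#'
#' The interquartile ranges are computed from the pooled ZIP x day true
#' series of this iteration, for use in IQR standardisation of the assumed
#' relative risks.
#'
#' @param panel Exposure panel (provides the unrefined metric).
#' @param calib A `calibration_set` from [fit_calibrations()] for the same
#'   error type.
#' @param pol1,pol2 Main pollutant and copollutant labels.
#' @param error_type One of `"spatial"`, `"population"`, `"total"`.
#' @return An object of class `true_exposure_pair`: list with `exposures`
#'   (tibble `zip_id`, `day`, `exp1`, `exp2`), `iqr1`, `iqr2`,
#'   `theta_draws` (tibble of the realised coefficients per zip x
#'   pollutant), `pol1`, `pol2`, `error_type`.  Uses the current RNG
#'   stream; seed with `set.seed()` for reproducibility.
#' @export
simulate_true_exposure <- function(panel, calib, pol1, pol2,
                                   error_type = calib$error_type) {
  stopifnot(inherits(calib, "calibration_set"))
  if (!identical(error_type, calib$error_type)) {
    stop("calibration set was fitted for error type '", calib$error_type,
         "', not '", error_type, "'", call. = FALSE)
  }
  mets <- error_type_metrics(error_type)
  unref <- panel[panel$metric == mets["unrefined"] &
                   panel$pollutant %in% c(pol1, pol2), ]
  wide <- tidyr::pivot_wider(unref[, c("zip_id", "day", "pollutant", "value")],
                             names_from = "pollutant", values_from = "value")
  wide <- dplyr::arrange(wide, .data$zip_id, .data$day)
  if (!all(c(pol1, pol2) %in% names(wide))) {
    stop("panel lacks pollutant ", setdiff(c(pol1, pol2), names(wide))[1],
         call. = FALSE)
  }

  th <- calib$theta
  zips <- unique(wide$zip_id)
  exp1 <- numeric(nrow(wide))
  exp2 <- numeric(nrow(wide))
  draws <- list()
  for (z in zips) {
    rows <- which(wide$zip_id == z)
    sig <- pair_resid_cov(calib, z, pol1, pol2)
    eps <- MASS::mvrnorm(length(rows), mu = c(0, 0), Sigma = sig)
    eps <- matrix(eps, ncol = 2)
    for (j in 1:2) {
      p <- c(pol1, pol2)[j]
      row <- th[th$zip_id == z & th$pollutant == p, ]
      if (nrow(row) != 1) {
        stop(sprintf("calibration set lacks (zip %s, pollutant %s)", z, p),
             call. = FALSE)
      }
      tcov <- matrix(c(row$cov11, row$cov12, row$cov12, row$cov22), 2, 2)
      theta <- drop(MASS::mvrnorm(1, mu = c(row$theta1, row$theta2),
                                  Sigma = tcov))
      val <- theta[1] + theta[2] * wide[[p]][rows] + eps[, j]
      if (j == 1) exp1[rows] <- val else exp2[rows] <- val
      draws[[paste(z, p)]] <- tibble::tibble(
        zip_id = z, pollutant = p, theta1 = theta[1], theta2 = theta[2])
    }
  }

  iqr1 <- stats::IQR(exp1)
  iqr2 <- stats::IQR(exp2)
  if (!(iqr1 > 0) || !(iqr2 > 0)) {
    stop("degenerate true exposure: interquartile range is zero",
         call. = FALSE)
  }
  structure(
    list(exposures = tibble::tibble(zip_id = wide$zip_id, day = wide$day,
                                    exp1 = exp1, exp2 = exp2),
         iqr1 = iqr1, iqr2 = iqr2,
         theta_draws = dplyr::bind_rows(draws),
         pol1 = pol1, pol2 = pol2, error_type = error_type),
    class = "true_exposure_pair"
  )
}

#' Write a true-exposure pair to CSV (debugging aid)
#'
#' @param pair A `true_exposure_pair`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_true_exposure <- function(pair, path) {
  out <- pair$exposures
  names(out)[names(out) == "exp1"] <- paste0("true_", pair$pol1)
  names(out)[names(out) == "exp2"] <- paste0("true_", pair$pol2)
  readr::write_csv(out, path)
  invisible(path)
}
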