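#' Decompose an exposure panel into measurement-error components
#'
#' For every (zip, day, pollutant) computes the three exposure-error deltas
#' between pairs of metrics: `spatial = AQ - CS` (error from assigning the
#' central-site value to every ZIP), `population = PE - AQ` (error from
#' ignoring human activity and infiltration), and `total = PE - CS`.  By
#' construction `spatial + population = total` for every cell.
#'
#' @param panel An exposure panel with all three metrics per cell.
#' @return Tibble `zip_id`, `day`, `date`, `pollutant`, `error_type`
#'   (`"spatial"`, `"population"`, `"total"`), `delta` (concentration
#'   difference in pollutant units).
#' @export
compute_error_panel <- function(panel) {
  wide <- panel_wide(panel)
  long <- tidyr::pivot_longer(
    dplyr::transmute(wide,
                     .data$zip_id, .data$day, .data$date, .data$pollutant,
                     spatial = .data$AQ - .data$CS,
                     population = .data$PE - .data$AQ,
                     total = .data$PE - .data$CS),
    cols = c("spatial", "population", "total"),
    names_to = "error_type", values_to = "delta"
  )
  dplyr::arrange(long, .data$zip_id, .data$day, .data$pollutant,
                 .data$error_type)
}

# one row per (zip, day, pollutant) with CS/AQ/PE columns; errors on any
# missing metric, naming the first incomplete tuple
panel_wide <- function(panel) {
  wide <- tidyr::pivot_wider(panel, names_from = "metric",
                             values_from = "value")
  for (m in c("CS", "AQ", "PE")) {
    if (!m %in% names(wide)) {
      stop(sprintf("panel has no '%s' metric", m), call. = FALSE)
    }
    bad <- which(is.na(wide[[m]]))
    if (length(bad) > 0) {
      i <- bad[1]
      stop(sprintf("missing metric %s for (zip %s, day %d, pollutant %s)",
                   m, wide$zip_id[i], wide$day[i], wide$pollutant[i]),
           call. = FALSE)
    }
  }
  wide
}

# which metric predicts which for a given error type
error_type_metrics <- function(error_type) {
  switch(error_type,
         spatial    = c(unrefined = "CS", refined = "AQ"),
         population = c(unrefined = "AQ", refined = "PE"),
         total      = c(unrefined = "CS", refined = "PE"),
         stop("unknown error_type: ", error_type, call. = FALSE))
}

#' Estimate ZIP-specific calibrations between exposure metrics
#'
#' For one error type, fits the ordinary least-squares calibration
#' `refined = theta1 + theta2 * unrefined + eps` separately for each ZIP
#' code and each pollutant, where the unrefined predictor is `CS` for
#' spatial and total error and `AQ` for population error.  Alongside the
#' intercept (additive bias) and slope (multiplicative bias) it records the
#' homoskedastic asymptotic covariance of `(theta1, theta2)`,
#' `sigma2 * (X'X)^{-1}`, and — for every pollutant pair within a ZIP — the
#' empirical covariance of the two fits' residuals paired by day
#' (denominator `n - 2`, matching the residual-variance estimator, so each
#' diagonal equals the single-pollutant residual variance).
#'
#' @param panel An exposure panel with all three metrics.
#' @param error_type One of `"spatial"`, `"population"`, `"total"`.
#' @return An object of class `calibration_set`: list with `theta` (tibble:
#'   `zip_id`, `pollutant`, `error_type`, `theta1`, `theta2`, `cov11`,
#'   `cov12`, `cov22`, `resid_var`, `n_days`) and `resid_cov` (tibble:
#'   `zip_id`, `pollutant_a`, `pollutant_b`, `error_type`, `cov_ab`).
#' @export
fit_calibrations <- function(panel, error_type = c("spatial", "population",
                                                   "total")) {
  error_type <- match.arg(error_type)
  mets <- error_type_metrics(error_type)
  wide <- panel_wide(panel)
  wide <- wide[stats::complete.cases(wide[, c(mets["unrefined"],
                                              mets["refined"])]), ]

  zips <- unique(wide$zip_id)
  pols <- unique(wide$pollutant)

  theta_rows <- list()
  cov_rows <- list()
  for (z in zips) {
    sub <- wide[wide$zip_id == z, ]
    resids <- list()
    for (p in pols) {
      sp <- sub[sub$pollutant == p, ]
      sp <- sp[order(sp$day), ]
      x <- sp[[mets["unrefined"]]]
      y <- sp[[mets["refined"]]]
      n <- length(x)
      if (n < 10) {
        stop(sprintf("fewer than 10 days for (zip %s, pollutant %s)", z, p),
             call. = FALSE)
      }
      if (var(x) == 0) {
        stop(sprintf("constant predictor for (zip %s, pollutant %s): slope unidentifiable",
                     z, p), call. = FALSE)
      }
      xb <- mean(x); sxx <- sum((x - xb)^2)
      theta2 <- sum((x - xb) * (y - mean(y))) / sxx
      theta1 <- mean(y) - theta2 * xb
      r <- y - theta1 - theta2 * x
      s2 <- sum(r^2) / (n - 2)
      # sigma2 * (X'X)^{-1} for X = [1, x]
      cov11 <- s2 * sum(x^2) / (n * sxx)
      cov12 <- -s2 * xb / sxx
      cov22 <- s2 / sxx
      theta_rows[[paste(z, p)]] <- tibble::tibble(
        zip_id = z, pollutant = p, error_type = error_type,
        theta1 = theta1, theta2 = theta2,
        cov11 = cov11, cov12 = cov12, cov22 = cov22,
        resid_var = s2, n_days = n
      )
      resids[[p]] <- stats::setNames(r, sp$day)
    }
    if (length(pols) > 1) {
      pairs <- utils::combn(pols, 2)
      for (j in seq_len(ncol(pairs))) {
        a <- pairs[1, j]; b <- pairs[2, j]
        common <- intersect(names(resids[[a]]), names(resids[[b]]))
        ra <- resids[[a]][common]; rb <- resids[[b]][common]
        cov_rows[[paste(z, a, b)]] <- tibble::tibble(
          zip_id = z, pollutant_a = a, pollutant_b = b,
          error_type = error_type,
          cov_ab = sum(ra * rb) / (length(common) - 2)
        )
      }
    }
  }
  structure(
    list(theta = dplyr::bind_rows(theta_rows),
         resid_cov = dplyr::bind_rows(cov_rows),
         error_type = error_type),
    class = "calibration_set"
  )
}

# 2x2 residual covariance for a pollutant pair within a ZIP; errors if the
# matrix is not positive semi-definite
pair_resid_cov <- function(calib, zip, pol1, pol2) {
  th <- calib$theta
  v1 <- th$resid_var[th$zip_id == zip & th$pollutant == pol1]
  v2 <- th$resid_var[th$zip_id == zip & th$pollutant == pol2]
  rc <- calib$resid_cov
  hit <- rc[rc$zip_id == zip &
              ((rc$pollutant_a == pol1 & rc$pollutant_b == pol2) |
                 (rc$pollutant_a == pol2 & rc$pollutant_b == pol1)), ]
  if (length(v1) != 1 || length(v2) != 1 || nrow(hit) != 1) {
    stop(sprintf("calibration set lacks pair (%s, %s) in zip %s",
                 pol1, pol2, zip), call. = FALSE)
  }
  m <- matrix(c(v1, hit$cov_ab, hit$cov_ab, v2), 2, 2)
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1)) {
    stop(sprintf("residual covariance for (%s, %s) in zip %s is not positive semi-definite",
                 pol1, pol2, zip), call. = FALSE)
  }
  m
}

#' Serialize a calibration set to CSV
#'
#' Writes two files for audit: `<stem>_theta.csv` (one row per zip x
#' pollutant with the calibration estimates and their covariance) and
#' `<stem>_residcov.csv` (one row per zip x pollutant pair).
#'
#' @param calib A `calibration_set`.
#' @param stem Path stem (without extension).
#' @return The two paths, invisibly.
#' @export
write_calibrations <- function(calib, stem) {
  p1 <- paste0(stem, "_theta.csv")
  p2 <- paste0(stem, "_residcov.csv")
  readr::write_csv(calib$theta, p1)
  readr::write_csv(calib$resid_cov, p2)
  invisible(c(p1, p2))
}

#' @export
print.calibration_set <- function(x, ...) {
  cat(sprintf("<calibration_set> %s error: %d zip x pollutant fits, %d residual pairs\n",
              x$error_type, nrow(x$theta), nrow(x$resid_cov)))
  invisible(x)
}
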