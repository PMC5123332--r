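#' Build the health-model design matrix
#'
#' Assembles the covariate matrix of the Poisson time-series model for daily
#' respiratory ED counts, without the two pollutant terms: an intercept, ZIP
#' indicators, day-of-week and holiday indicators, per-hospital activity
#' indicators, a cubic B-spline in calendar time with knots at the first day
#' of each month, one indicator per observed integer degree of maximum
#' temperature (reference: the coldest observed bin), cubic polynomials in
#' dew point and minimum temperature, and season indicators.  One reference
#' level is dropped from every categorical block; any remaining exactly
#' aliased columns (for example a hospital active on every day, or season
#' indicators absorbed by the spline) are detected by a QR rank check,
#' dropped, and reported via a message.
#'
#' @param covariates A covariate table from [generate_covariates()].
#' @return An object of class `health_design`: list with `X` (the design
#'   matrix), `zip_id`/`day` row index vectors, `blocks` (column-name list
#'   per block) and `dropped` (aliased columns removed).
#' @export
build_design_matrix <- function(covariates) {
  cov <- dplyr::arrange(covariates, .data$zip_id, .data$day)
  n <- nrow(cov)

  blocks <- list()
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  blocks$intercept <- "(Intercept)"

  add_block <- function(X, M, name) {
    blocks[[name]] <<- colnames(M)
    cbind(X, M)
  }
  indicators <- function(f, prefix) {
    f <- droplevels(as.factor(f))
    if (nlevels(f) < 2) return(NULL)
    M <- stats::model.matrix(~ f)[, -1, drop = FALSE]
    colnames(M) <- paste0(prefix, levels(f)[-1])
    M
  }

  m <- indicators(cov$zip_id, "zip_")
  if (!is.null(m)) X <- add_block(X, m, "zip")
  m <- indicators(cov$day_of_week, "dow_")
  if (!is.null(m)) X <- add_block(X, m, "dow")
  if (length(unique(cov$holiday)) > 1) {
    X <- add_block(X, matrix(as.numeric(cov$holiday), n, 1,
                             dimnames = list(NULL, "holiday")), "holiday")
  }

  hosp_cols <- grep("^hosp_", names(cov), value = TRUE)
  if (length(hosp_cols) > 0) {
    M <- as.matrix(cov[, hosp_cols])
    keep <- apply(M, 2, function(x) length(unique(x)) > 1)
    # hospitals active the whole study are aliased with the intercept
    if (any(keep)) X <- add_block(X, M[, keep, drop = FALSE], "hospital")
  }

  M <- time_spline_basis(cov$date, cov$time)
  X <- add_block(X, M, "time_spline")

  m <- indicators(cov$max_temp, "maxtemp_")
  if (!is.null(m)) X <- add_block(X, m, "max_temp")

  poly3 <- function(x, prefix) {
    # centred and scaled raw cubic, for numerical conditioning
    z <- (x - mean(x)) / sd(x)
    M <- cbind(z, z^2, z^3)
    colnames(M) <- paste0(prefix, 1:3)
    M
  }
  if (sd(cov$dew_point) > 0) X <- add_block(X, poly3(cov$dew_point, "dewpt_"), "dew_point")
  if (sd(cov$min_temp) > 0) X <- add_block(X, poly3(cov$min_temp, "mintemp_"), "min_temp")
  m <- indicators(cov$season, "season_")
  if (!is.null(m)) X <- add_block(X, m, "season")

  # exact-aliasing check
  qrX <- qr(X)
  dropped <- character(0)
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    dropped <- colnames(X)[-keep]
    message("build_design_matrix: dropping aliased columns: ",
            paste(dropped, collapse = ", "))
    X <- X[, sort(keep), drop = FALSE]
    blocks <- lapply(blocks, setdiff, y = dropped)
  }

  structure(
    list(X = X, zip_id = cov$zip_id, day = cov$day,
         blocks = blocks, dropped = dropped),
    class = "health_design"
  )
}

# Cubic B-spline basis in calendar time with interior knots at the first
# day of every month strictly inside the study period.
time_spline_basis <- function(date, time) {
  udate <- sort(unique(date))
  utime <- sort(unique(time))
  month_start <- udate[format(udate, "%d") == "01"]
  month_start <- month_start[month_start > min(udate) & month_start < max(udate)]
  knots <- utime[match(month_start, udate)]
  M <- splines::bs(time, knots = knots, degree = 3, intercept = FALSE)
  M <- matrix(as.numeric(M), nrow = length(time), ncol = ncol(M))
  colnames(M) <- paste0("spline_", seq_len(ncol(M)))
  M
}

#' Simulate Poisson health counts under assumed pollutant effects
#'
#' Computes the Poisson mean per (zip, day) as
#' `mu = exp(X B + log(rr1) * true1 / iqr1 + log(rr2) * true2 / iqr2)` and
#' draws independent Poisson counts.  With `rr1 = rr2 = 1` the mean reduces
#' to the exposure-free baseline `exp(X B)`.
#'
#' @param design A `health_design`.
#' @param B Coefficient vector aligned to `colnames(design$X)`.
#' @param true_pair A [true_exposure_pair][simulate_true_exposure] (or any
#'   list with `exposures` ordered like the design rows and `iqr1`, `iqr2`),
#'   or `NULL` for baseline-only counts.
#' @param rr1,rr2 Relative risks per IQR (> 0).
#' @return Tibble `zip_id`, `day`, `count`, plus attribute `"mu"`.
#' @export
simulate_counts <- function(design, B, true_pair = NULL, rr1 = 1, rr2 = 1) {
  stopifnot(inherits(design, "health_design"), rr1 > 0, rr2 > 0)
  B <- align_coefficients(B, design)
  eta <- drop(design$X %*% B)
  if (!is.null(true_pair)) {
    ex <- align_exposures(true_pair, design)
    eta <- eta + log(rr1) * ex[, 1] + log(rr2) * ex[, 2]
  }
  mu <- exp(eta)
  bad <- which(!is.finite(mu))
  if (length(bad) > 0) {
    stop(sprintf("non-finite Poisson mean at row %d (zip %s, day %d)",
                 bad[1], design$zip_id[bad[1]], design$day[bad[1]]),
         call. = FALSE)
  }
  out <- tibble::tibble(zip_id = design$zip_id, day = design$day,
                        count = rpois(length(mu), mu))
  attr(out, "mu") <- mu
  out
}

align_coefficients <- function(B, design) {
  cols <- colnames(design$X)
  if (!is.null(names(B))) {
    missing <- setdiff(cols, names(B))
    if (length(missing) > 0) {
      stop("coefficient vector missing design columns: ",
           paste(head(missing, 5), collapse = ", "), call. = FALSE)
    }
    B <- B[cols]
  } else if (length(B) != length(cols)) {
    stop("unnamed coefficient vector of wrong length", call. = FALSE)
  }
  B
}

# IQR-standardised exposure matrix in design row order
align_exposures <- function(true_pair, design) {
  ex <- true_pair$exposures
  key_design <- paste(design$zip_id, design$day)
  idx <- match(key_design, paste(ex$zip_id, ex$day))
  if (anyNA(idx)) stop("exposure support does not match the design rows",
                       call. = FALSE)
  cbind(ex$exp1[idx] / true_pair$iqr1, ex$exp2[idx] / true_pair$iqr2)
}

#' Fit the copollutant Poisson model
#'
#' Maximum-likelihood Poisson regression of the counts on the full design
#' plus the two IQR-standardised exposure series, via iteratively reweighted
#' least squares (relative deviance tolerance 1e-8, at most 100 iterations).
#' Returns the two exposure coefficients (log RR per IQR) with their
#' asymptotic standard errors.  Rank deficiency involving an exposure column
#' (an all-zero series, or the same series entered as both pollutants) is
#' flagged rather than raised.
#'
#' @param design A `health_design`.
#' @param counts Count tibble (`zip_id`, `day`, `count`) or a count vector
#'   in design row order.
#' @param exp1_std,exp2_std Exposure series in design row order, already
#'   standardised by their IQR.
#' @param start Optional starting coefficient vector for the covariate block
#'   (warm start, e.g. the baseline coefficients).
#' @return List: `beta1`, `beta2`, `se1`, `se2`, `converged`,
#'   `rank_deficient`, and `coefficients` (the full fitted vector).
#' @export
fit_copollutant_model <- function(design, counts, exp1_std, exp2_std,
                                  start = NULL) {
  stopifnot(inherits(design, "health_design"))
  y <- counts_vector(counts, design)
  X <- cbind(design$X, pollutant_1 = exp1_std, pollutant_2 = exp2_std)
  st <- NULL
  if (!is.null(start)) st <- c(align_coefficients(start, design), 0, 0)
  fit <- poisson_irls(X, y, start = st)
  cf <- fit$coefficients
  se <- fit$se
  rank_def <- anyNA(cf[c("pollutant_1", "pollutant_2")])
  list(beta1 = unname(cf["pollutant_1"]), beta2 = unname(cf["pollutant_2"]),
       se1 = unname(se["pollutant_1"]), se2 = unname(se["pollutant_2"]),
       converged = fit$converged && !rank_def,
       rank_deficient = rank_def, coefficients = cf)
}

counts_vector <- function(counts, design) {
  if (is.numeric(counts)) {
    stopifnot(length(counts) == nrow(design$X))
    return(counts)
  }
  idx <- match(paste(design$zip_id, design$day),
               paste(counts$zip_id, counts$day))
  if (anyNA(idx)) stop("count support does not match the design rows",
                       call. = FALSE)
  counts$count[idx]
}

# Poisson IRLS via stats::glm.fit; coefficient covariance from the R factor
# of the final weighted least-squares problem (dispersion fixed at 1).
poisson_irls <- function(X, y, start = NULL) {
  fit <- suppressWarnings(stats::glm.fit(
    x = X, y = y, family = stats::poisson(),
    start = start,
    control = stats::glm.control(epsilon = 1e-8, maxit = 100)
  ))
  p1 <- seq_len(fit$rank)
  cov_unscaled <- chol2inv(fit$qr$qr[p1, p1, drop = FALSE])
  se <- rep(NA_real_, ncol(X))
  names(se) <- colnames(X)
  se[fit$qr$pivot[p1]] <- sqrt(diag(cov_unscaled))
  list(coefficients = fit$coefficients, se = se,
       converged = fit$converged, rank = fit$rank,
       deviance = fit$deviance, iter = fit$iter)
}

#' Fit the baseline (pollutant-free) Poisson model
#'
#' Fits the health model without the two pollutant terms and returns the
#' estimated coefficient vector aligned to the design columns, for use as
#' the baseline `B` when simulating outcomes.
#'
#' @param covariates Covariate table, or a prebuilt `health_design`.
#' @param counts Count tibble (`zip_id`, `day`, `count`) of nonnegative
#'   integers, one per (zip, day).
#' @return Named coefficient vector `B` with attributes `"se"` and
#'   `"design"` (the `health_design` used).
#' @export
fit_baseline_coefficients <- function(covariates, counts) {
  design <- if (inherits(covariates, "health_design")) covariates
            else build_design_matrix(covariates)
  y <- counts_vector(counts, design)
  if (any(y < 0) || any(y != round(y))) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  if (all(y == 0)) {
    stop("degenerate input: all counts are zero (intercept diverges to -Inf)",
         call. = FALSE)
  }
  fit <- poisson_irls(design$X, y)
  if (!fit$converged) {
    stop(sprintf("baseline Poisson fit did not converge after %d iterations (deviance %.4g)",
                 fit$iter, fit$deviance), call. = FALSE)
  }
  structure(fit$coefficients, se = fit$se, design = design)
}

#' Reference baseline coefficients for a synthetic scenario
#'
#' A deterministic, plausible coefficient vector for the baseline model:
#' mild ZIP and weekend effects, a holiday dip, small hospital and weather
#' effects, and an intercept chosen so the average Poisson mean equals the
#' scenario's `baseline_rate`.  Used to generate baseline counts from which
#' [fit_baseline_coefficients()] re-estimates `B`, so that coefficient
#' recovery is testable.
#'
#' @param design A `health_design`.
#' @param baseline_rate Target mean counts per ZIP-day.
#' @return Named coefficient vector aligned to `colnames(design$X)`.
#' @export
default_baseline_coefficients <- function(design, baseline_rate = 2) {
  cols <- colnames(design$X)
  B <- setNames(rep(0, length(cols)), cols)
  bl <- design$blocks
  set_blk <- function(B, names, values) {
    if (length(names) > 0) B[names] <- rep_len(values, length(names))
    B
  }
  B <- set_blk(B, bl$zip, seq(-0.15, 0.15, length.out = max(1, length(bl$zip))))
  B <- set_blk(B, intersect(c("dow_Sat", "dow_Sun"), bl$dow), -0.10)
  B <- set_blk(B, bl$holiday, -0.15)
  B <- set_blk(B, bl$hospital, 0.08)
  B <- set_blk(B, bl$season, c(0.05, -0.05, 0.02))
  B <- set_blk(B, bl$dew_point, c(0.02, -0.01, 0))
  B <- set_blk(B, bl$min_temp, c(-0.03, 0.01, 0))
  # winter peak in respiratory visits via a gentle cosine mapped onto time
  if (length(bl$time_spline) > 0) {
    k <- length(bl$time_spline)
    B[bl$time_spline] <- 0.15 * cos(2 * pi * seq_len(k) / (k / 2))
  }
  eta <- drop(design$X %*% B)
  B["(Intercept)"] <- log(baseline_rate) - log(mean(exp(eta)))
  B
}

#' Read or write a count panel as CSV
#'
#' Columns: `zip_id`, `date` (ISO-8601 if available) or `day`, `count`.
#'
#' @param counts Count tibble.
#' @param path File path.
#' @return `read_counts()` returns the tibble; `write_counts()` returns
#'   `path` invisibly.
#' @export
write_counts <- function(counts, path) {
  readr::write_csv(counts, path)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
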