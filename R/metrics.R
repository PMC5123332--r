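#' Monte Carlo summary statistics for copollutant simulations
#'
#' These helpers turn streams of per-iteration log relative-risk estimates
#' into the summary statistics of the simulation study: the mean RR
#' (exponential of the mean log RR), percent attenuation of the assumed
#' excess risk, root-mean-square error of the log RR and the noisy/true
#' RMSE ratio, power or type I error with its binomial standard error,
#' 95% confidence-interval coverage, and a Welch t-test comparing estimate
#' streams across copollutants.
#'
#' @name metrics
NULL

#' @describeIn metrics Mean relative risk: `exp(mean(betas))`, the
#'   geometric-mean RR across iterations.
#' @param betas Numeric vector of log relative risks per IQR (one per
#'   Monte Carlo iteration).
#' @export
mean_rr <- function(betas) {
  if (length(betas) == 0) stop("empty estimate stream", call. = FALSE)
  exp(mean(betas))
}

#' @describeIn metrics Percent attenuation of the assumed relative risk:
#'   `100 * (rr_assumed - rr_mean) / (rr_assumed - 1)`.  Negative values
#'   indicate bias away from the null; values above 100 indicate
#'   overshooting it.  Undefined for a null assumed RR.
#' @param rr_assumed The relative risk the counts were simulated under.
#' @param rr_mean The mean estimated RR (e.g. from [mean_rr()]).
#' @export
percent_attenuation <- function(rr_assumed, rr_mean) {
  if (rr_assumed == 1) {
    stop("percent attenuation is undefined for a null assumed RR (rr = 1)",
         call. = FALSE)
  }
  100 * (rr_assumed - rr_mean) / (rr_assumed - 1)
}

#' @describeIn metrics Root-mean-square error of the log RR about the
#'   assumed value: `sqrt(mean((betas - log(rr_assumed))^2))`.
#' @export
rmse <- function(betas, rr_assumed) {
  if (length(betas) == 0) stop("empty estimate stream", call. = FALSE)
  sqrt(mean((betas - log(rr_assumed))^2))
}

#' @describeIn metrics RMSE ratio `rmse_noisy / rmse_true`, the combined
#'   bias-and-precision penalty of the error-prone exposure.
#' @param rmse_noisy,rmse_true RMSEs from the noisy- and true-exposure fits.
#' @export
rmse_ratio <- function(rmse_noisy, rmse_true) {
  if (!(rmse_true > 0)) stop("rmse_true must be > 0", call. = FALSE)
  rmse_noisy / rmse_true
}

#' @describeIn metrics Power (or, under a null effect, type I error): the
#'   proportion of iterations whose standardised coefficient `beta/se`
#'   exceeds 1.96 — in absolute value when `two_sided` (the default, whose
#'   null rate is 0.05), or signed one-sided otherwise (null rate 0.025).
#'   The standard error is the binomial `sqrt(p * (1 - p) / N)`.
#' @param ses Standard errors matching `betas`.
#' @param two_sided Use `|z| > 1.96` (default) rather than `z > 1.96`.
#' @return `power_type1()` returns a list with `proportion` and `se`.
#' @export
power_type1 <- function(betas, ses, two_sided = TRUE) {
  if (length(betas) == 0 || length(betas) != length(ses)) {
    stop("betas and ses must be non-empty and of equal length", call. = FALSE)
  }
  if (any(ses <= 0)) stop("all standard errors must be > 0", call. = FALSE)
  z <- betas / ses
  hit <- if (two_sided) abs(z) > 1.96 else z > 1.96
  p <- mean(hit)
  list(proportion = p, se = sqrt(p * (1 - p) / length(betas)))
}

#' @describeIn metrics Empirical coverage of the nominal 95% confidence
#'   interval: the fraction of iterations with
#'   `true_log_rr` inside `beta +/- 1.96 * se`.
#' @param true_log_rr The log of the assumed RR.
#' @export
ci_coverage <- function(betas, ses, true_log_rr) {
  if (length(betas) == 0 || length(betas) != length(ses)) {
    stop("betas and ses must be non-empty and of equal length", call. = FALSE)
  }
  if (any(ses <= 0)) stop("all standard errors must be > 0", call. = FALSE)
  mean(betas - 1.96 * ses <= true_log_rr & true_log_rr <= betas + 1.96 * ses)
}

#' @describeIn metrics Welch two-sample two-sided t-test between two
#'   estimate streams (e.g. the main-pollutant log RRs under two different
#'   copollutants).  Returns a list with `t` and `p_value`.
#' @param betas_a,betas_b The two estimate streams.
#' @export
compare_copollutants <- function(betas_a, betas_b) {
  if (length(betas_a) < 2 || length(betas_b) < 2) {
    stop("both estimate streams must have length >= 2", call. = FALSE)
  }
  if (sd(betas_a) == 0 && sd(betas_b) == 0 &&
      mean(betas_a) == mean(betas_b)) {
    return(list(t = 0, p_value = 1))
  }
  ht <- t.test(betas_a, betas_b, alternative = "two.sided")
  list(t = unname(ht$statistic), p_value = unname(ht$p.value))
}

#' Summarise a scenario result into the metrics table row
#'
#' Computes, for the main pollutant and the copollutant and for both the
#' true- and noisy-exposure fits: the mean RR with two spreads (the SD of
#' the log-RR stream and the SD divided by sqrt(N), the Monte Carlo
#' standard error of the reported mean), percent attenuation of the main
#' pollutant under the noisy fit (and the true fit, for reference), RMSEs
#' and the noisy/true RMSE ratio, power or type I error with binomial SE,
#' 95% CI coverage, and the 2.5th/97.5th percentiles of the estimated RRs.
#'
#' @param result A `scenario_result`.
#' @param two_sided Significance rule passed to [power_type1()].
#' @return One-row tibble (a `MetricsTable` row).
#' @export
summarize_scenario <- function(result, two_sided = TRUE) {
  it <- result$iterations
  sc <- result$scenario
  n <- nrow(it)
  stopifnot(n > 0)

  one <- function(betas, ses, rr_assumed, prefix) {
    m <- mean_rr(betas)
    pw <- power_type1(betas, ses, two_sided = two_sided)
    out <- tibble::tibble(
      mean_rr = m,
      sd_log_rr = sd(betas),
      se_mean_log_rr = sd(betas) / sqrt(length(betas)),
      rr_p2.5 = exp(quantile(betas, 0.025, names = FALSE)),
      rr_p97.5 = exp(quantile(betas, 0.975, names = FALSE)),
      rmse = rmse(betas, rr_assumed),
      power_or_type1 = pw$proportion,
      power_se = pw$se,
      coverage95 = ci_coverage(betas, ses, log(rr_assumed))
    )
    names(out) <- paste0(prefix, "_", names(out))
    out
  }

  blocks <- dplyr::bind_cols(
    one(it$beta1_true, it$se1_true, sc$rr1, "main_true"),
    one(it$beta1_noisy, it$se1_noisy, sc$rr1, "main_noisy"),
    one(it$beta2_true, it$se2_true, sc$rr2, "co_true"),
    one(it$beta2_noisy, it$se2_noisy, sc$rr2, "co_noisy")
  )

  att_noisy <- if (sc$rr1 != 1) {
    percent_attenuation(sc$rr1, blocks$main_noisy_mean_rr)
  } else NA_real_
  att_true <- if (sc$rr1 != 1) {
    percent_attenuation(sc$rr1, blocks$main_true_mean_rr)
  } else NA_real_

  dplyr::bind_cols(
    tibble::tibble(pol1 = sc$pol1, pol2 = sc$pol2,
                   error_type = sc$error_type,
                   rr1 = sc$rr1, rr2 = sc$rr2, n_iterations = n),
    tibble::tibble(pct_attenuation = att_noisy,
                   pct_attenuation_true = att_true),
    blocks,
    tibble::tibble(
      main_rmse_ratio = rmse_ratio(blocks$main_noisy_rmse,
                                   blocks$main_true_rmse),
      co_rmse_ratio = rmse_ratio(blocks$co_noisy_rmse, blocks$co_true_rmse)
    )
  )
}

#' Summarise many scenario results
#'
#' @param results List of `scenario_result` (error entries are skipped).
#' @param two_sided Passed to [summarize_scenario()].
#' @return Tibble with one row per scenario.
#' @export
summarize_grid <- function(results, two_sided = TRUE) {
  ok <- Filter(function(x) inherits(x, "scenario_result"), results)
  dplyr::bind_rows(lapply(ok, summarize_scenario, two_sided = two_sided))
}
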