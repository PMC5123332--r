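#' Run the Monte Carlo experiment for one scenario
#'
#' One scenario is a (main pollutant, copollutant, error type) cell.  Each
#' iteration simulates a true exposure pair from the calibration structure,
#' simulates Poisson counts under the assumed relative risks, and fits the
#' copollutant health model twice on the same counts: once with the
#' simulated true exposures and once with the unrefined, error-prone
#' exposures (CS for spatial/total error, AQ for population error), both
#' standardised by their interquartile ranges.  The true-exposure IQRs are
#' those of the iteration's simulated series; the unrefined IQRs are those
#' of the observed unrefined series, fixed across iterations.
#'
#' Per-iteration seeds are derived from the master seed by a documented
#' counter scheme (`iteration_seed()`), so runs are reproducible and
#' individual iterations can be replayed in isolation.  Iterations whose
#' fits fail to converge are dropped and counted; if more than 1% of
#' iterations fail the scenario errors out with diagnostics.
#'
#' @param config A [scenario_config()] (supplies `rr_main`, `rr_co`,
#'   `n_iterations`, `seed`).
#' @param panel Exposure panel.
#' @param calib A `calibration_set` for `error_type`.
#' @param B Baseline coefficient vector aligned to `design`.
#' @param pol1,pol2 Main pollutant and copollutant labels.
#' @param error_type One of `"spatial"`, `"population"`, `"total"`.
#' @param design The `health_design` built from the scenario covariates
#'   (prebuilt once and shared across scenarios).
#' @param n_iterations,master_seed Optional overrides of the config values.
#' @param scenario_index Integer offsetting the seed stream so grid cells
#'   use independent substreams.
#' @return An object of class `scenario_result`: list with `scenario`
#'   (descriptor list), `iterations` (tibble with one row per converged
#'   iteration: `iteration`, `seed`, `beta1_true`, `beta2_true`, `se1_true`,
#'   `se2_true`, `beta1_noisy`, `beta2_noisy`, `se1_noisy`, `se2_noisy`),
#'   `n_requested`, `n_failed`.
#' @export
run_scenario <- function(config, panel, calib, B, pol1, pol2,
                         error_type = calib$error_type, design,
                         n_iterations = config$n_iterations,
                         master_seed = config$seed,
                         scenario_index = 0L) {
  stopifnot(inherits(design, "health_design"))
  mets <- error_type_metrics(error_type)

  # unrefined exposures, standardised by their (fixed) IQRs, in design order
  unref <- panel[panel$metric == mets["unrefined"], ]
  u1 <- exposure_in_design_order(unref, pol1, design)
  u2 <- exposure_in_design_order(unref, pol2, design)
  u1 <- u1 / stats::IQR(u1)
  u2 <- u2 / stats::IQR(u2)

  rows <- vector("list", n_iterations)
  n_failed <- 0L
  for (i in seq_len(n_iterations)) {
    seed_i <- iteration_seed(master_seed, scenario_index, i)
    set.seed(seed_i)
    pair <- simulate_true_exposure(panel, calib, pol1, pol2, error_type)
    counts <- simulate_counts(design, B, pair,
                              rr1 = config$rr_main, rr2 = config$rr_co)
    ex <- align_exposures(pair, design)
    fit_t <- fit_copollutant_model(design, counts$count, ex[, 1], ex[, 2],
                                   start = B)
    fit_n <- fit_copollutant_model(design, counts$count, u1, u2, start = B)
    if (!fit_t$converged || !fit_n$converged) {
      n_failed <- n_failed + 1L
      next
    }
    rows[[i]] <- tibble::tibble(
      iteration = i, seed = seed_i,
      beta1_true = fit_t$beta1, beta2_true = fit_t$beta2,
      se1_true = fit_t$se1, se2_true = fit_t$se2,
      beta1_noisy = fit_n$beta1, beta2_noisy = fit_n$beta2,
      se1_noisy = fit_n$se1, se2_noisy = fit_n$se2
    )
  }
  if (n_failed > 0.01 * n_iterations) {
    stop(sprintf("scenario (%s, %s, %s): %d of %d iterations failed to converge (cap 1%%)",
                 pol1, pol2, error_type, n_failed, n_iterations),
         call. = FALSE)
  }
  structure(
    list(
      scenario = list(pol1 = pol1, pol2 = pol2, error_type = error_type,
                      rr1 = config$rr_main, rr2 = config$rr_co,
                      master_seed = master_seed,
                      scenario_index = scenario_index),
      iterations = dplyr::bind_rows(rows),
      n_requested = n_iterations, n_failed = n_failed
    ),
    class = "scenario_result"
  )
}

exposure_in_design_order <- function(metric_panel, pollutant, design) {
  sub <- metric_panel[metric_panel$pollutant == pollutant, ]
  idx <- match(paste(design$zip_id, design$day),
               paste(sub$zip_id, sub$day))
  if (anyNA(idx)) {
    stop("panel support does not match the design rows for pollutant ",
         pollutant, call. = FALSE)
  }
  sub$value[idx]
}

#' Per-iteration seed derivation
#'
#' Deterministic counter scheme mapping (master seed, scenario index,
#' iteration) to a 31-bit seed: `(master * 2654435761 + scenario * 1000003 +
#' iteration) mod (2^31 - 1)`, using the golden-ratio multiplier to spread
#' nearby master seeds apart.
#'
#' @param master_seed,scenario_index,iteration Integers.
#' @return A positive integer seed.
#' @export
iteration_seed <- function(master_seed, scenario_index, iteration) {
  m <- (as.double(master_seed) * 2654435761) %% 2147483647
  as.integer((m + as.double(scenario_index) * 1000003 + iteration) %% 2147483647)
}

#' Run the full scenario grid
#'
#' Executes [run_scenario()] for every ordered pollutant pair and error
#' type, writing one result CSV per scenario into `out_dir` (if given) and
#' skipping scenarios whose result file already exists, so an interrupted
#' grid can be resumed.  Scenario failures are caught and reported at the
#' end rather than aborting the remaining cells.
#'
#' @param config A [scenario_config()].
#' @param panel,design,B As for [run_scenario()]; generated from the config
#'   when omitted.
#' @param pairs Optional two-column matrix/data frame of (pol1, pol2)
#'   labels; defaults to all ordered pairs of configured pollutants.
#' @param error_types Character vector of error types to run.
#' @param out_dir Optional directory for per-scenario CSVs.
#' @param quiet Suppress progress messages.
#' @return Named list of `scenario_result` (or condition objects for failed
#'   cells), one per scenario.
#' @export
run_grid <- function(config, panel = NULL, design = NULL, B = NULL,
                     pairs = NULL,
                     error_types = c("spatial", "population", "total"),
                     out_dir = NULL, quiet = FALSE) {
  validate_scenario(config)
  if (is.null(panel)) panel <- generate_exposure_panel(config)
  if (is.null(design)) design <- build_design_matrix(generate_covariates(config))
  if (is.null(B)) {
    B0 <- default_baseline_coefficients(design, config$baseline_rate)
    set.seed(config$seed + 2L)
    base_counts <- simulate_counts(design, B0)
    B <- fit_baseline_coefficients(design, base_counts)
  }
  pols <- config$pollutants$pollutant
  if (is.null(pairs)) {
    pairs <- expand.grid(pol1 = pols, pol2 = pols, stringsAsFactors = FALSE)
    pairs <- pairs[pairs$pol1 != pairs$pol2, ]
  }
  calibs <- lapply(setNames(error_types, error_types),
                   function(et) fit_calibrations(panel, et))

  results <- list()
  idx <- 0L
  for (et in error_types) {
    for (r in seq_len(nrow(pairs))) {
      idx <- idx + 1L
      p1 <- pairs$pol1[r]; p2 <- pairs$pol2[r]
      tag <- sprintf("%s_%s_%s", p1, p2, et)
      path <- if (!is.null(out_dir)) file.path(out_dir, paste0(tag, ".csv"))
      if (!is.null(path) && file.exists(path)) {
        if (!quiet) message("run_grid: ", tag, " already done, skipping")
        results[[tag]] <- read_scenario_result(path)
        next
      }
      if (!quiet) message(sprintf("run_grid: [%d] %s", idx, tag))
      res <- tryCatch(
        run_scenario(config, panel, calibs[[et]], B, p1, p2, et,
                     design = design, scenario_index = idx),
        error = function(e) e
      )
      if (!inherits(res, "error") && !is.null(path)) {
        write_scenario_result(res, path)
      }
      results[[tag]] <- res
    }
  }
  failed <- names(Filter(function(x) inherits(x, "error"), results))
  if (length(failed) > 0 && !quiet) {
    message("run_grid: failed scenarios: ", paste(failed, collapse = ", "))
  }
  results
}

#' Read or write a scenario result as CSV
#'
#' One row per iteration; scenario descriptor fields are repeated on each
#' row so files are self-describing.
#'
#' @param result A `scenario_result`.
#' @param path File path.
#' @return `read_scenario_result()` returns a `scenario_result`;
#'   `write_scenario_result()` returns `path` invisibly.
#' @export
write_scenario_result <- function(result, path) {
  sc <- result$scenario
  out <- dplyr::bind_cols(
    tibble::tibble(pol1 = sc$pol1, pol2 = sc$pol2,
                   error_type = sc$error_type,
                   rr1 = sc$rr1, rr2 = sc$rr2,
                   master_seed = sc$master_seed,
                   scenario_index = sc$scenario_index,
                   n_requested = result$n_requested,
                   n_failed = result$n_failed),
    result$iterations
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_scenario_result
#' @export
read_scenario_result <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("pol1", "pol2", "error_type", "rr1", "rr2", "beta1_true",
            "beta1_noisy", "se1_true", "se1_noisy")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0) {
    stop(sprintf("malformed scenario result %s: missing column %s",
                 path, miss[1]), call. = FALSE)
  }
  iter_cols <- c("iteration", "seed", "beta1_true", "beta2_true", "se1_true",
                 "se2_true", "beta1_noisy", "beta2_noisy", "se1_noisy",
                 "se2_noisy")
  structure(
    list(
      scenario = list(pol1 = raw$pol1[1], pol2 = raw$pol2[1],
                      error_type = raw$error_type[1],
                      rr1 = raw$rr1[1], rr2 = raw$rr2[1],
                      master_seed = raw$master_seed[1],
                      scenario_index = raw$scenario_index[1]),
      iterations = raw[, intersect(iter_cols, names(raw))],
      n_requested = raw$n_requested[1], n_failed = raw$n_failed[1]
    ),
    class = "scenario_result"
  )
}

#' @export
print.scenario_result <- function(x, ...) {
  sc <- x$scenario
  cat(sprintf("<scenario_result> main %s / co %s, %s error: %d iterations (%d failed)\n",
              sc$pol1, sc$pol2, sc$error_type, nrow(x$iterations), x$n_failed))
  invisible(x)
}
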