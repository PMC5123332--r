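#' Attenuation table by main pollutant and error type
#'
#' Percent attenuation of the main pollutant's noisy-fit RR, reported as a
#' min-max range across all copollutants paired with that main pollutant,
#' in a main pollutant x error type layout.
#'
#' @param metrics A metrics tibble from [summarize_grid()].
#' @return Tibble with one row per main pollutant and one column per error
#'   type, each cell a "lo-hi%" range string.
#' @export
attenuation_table <- function(metrics) {
  stopifnot(nrow(metrics) > 0)
  rng <- dplyr::summarise(
    dplyr::group_by(metrics, .data$pol1, .data$error_type),
    cell = {
      lo <- round(min(.data$pct_attenuation))
      hi <- round(max(.data$pct_attenuation))
      if (lo == hi) sprintf("%d%%", lo) else sprintf("%d-%d%%", lo, hi)
    },
    .groups = "drop"
  )
  tidyr::pivot_wider(rng, names_from = "error_type", values_from = "cell")
}

#' RMSE-ratio table by pollutant pair and error type
#'
#' Noisy/true RMSE ratios for the main pollutant and the copollutant, one
#' row per ordered pollutant pair, with a column pair per error type.
#'
#' @param metrics A metrics tibble from [summarize_grid()].
#' @return Tibble: `pol1`, `pol2`, then `<error_type>_main` and
#'   `<error_type>_co` columns.
#' @export
rmse_ratio_table <- function(metrics) {
  stopifnot(nrow(metrics) > 0)
  long <- dplyr::select(metrics, "pol1", "pol2", "error_type",
                        main = "main_rmse_ratio", co = "co_rmse_ratio")
  wide <- tidyr::pivot_wider(long, names_from = "error_type",
                             values_from = c("main", "co"),
                             names_glue = "{error_type}_{.value}")
  dplyr::arrange(wide, .data$pol1, .data$pol2)
}

#' Plot mean RR point estimates with percentile error bars
#'
#' Mean estimated RR for the main pollutant and copollutant, true and noisy
#' fits, with 2.5th-97.5th percentile bars across iterations, faceted by
#' error type.
#'
#' @param metrics A metrics tibble from [summarize_grid()].
#' @return A ggplot object.
#' @export
plot_rr_estimates <- function(metrics) {
  long <- dplyr::bind_rows(lapply(
    c("main_true", "main_noisy", "co_true", "co_noisy"),
    function(pfx) tibble::tibble(
      pair = paste(metrics$pol1, metrics$pol2, sep = "/"),
      error_type = metrics$error_type,
      role = sub("_.*", "", pfx),
      fit = sub(".*_", "", pfx),
      rr = metrics[[paste0(pfx, "_mean_rr")]],
      lo = metrics[[paste0(pfx, "_rr_p2.5")]],
      hi = metrics[[paste0(pfx, "_rr_p97.5")]]
    )
  ))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$pair, y = .data$rr,
                                     colour = .data$fit,
                                     shape = .data$role)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                             position = ggplot2::position_dodge(width = 0.6),
                             fatten = 2) +
    ggplot2::facet_wrap(~error_type, ncol = 1) +
    ggplot2::labs(x = "main pollutant / copollutant", y = "RR per IQR",
                  colour = "exposure", shape = "pollutant") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot copollutant type I error with a 0.05 reference line
#'
#' Noisy-fit type I error for the null copollutant per scenario, with
#' binomial error bars and a horizontal reference at 0.05.
#'
#' @param metrics A metrics tibble from [summarize_grid()].
#' @return A ggplot object.
#' @export
plot_type1_error <- function(metrics) {
  d <- tibble::tibble(
    pair = paste(metrics$pol1, metrics$pol2, sep = "/"),
    error_type = metrics$error_type,
    t1 = metrics$co_noisy_power_or_type1,
    se = metrics$co_noisy_power_se
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pair, y = .data$t1)) +
    ggplot2::geom_hline(yintercept = 0.05, colour = "red") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = pmax(.data$t1 - 1.96 * .data$se, 0),
                                          ymax = pmin(.data$t1 + 1.96 * .data$se, 1))) +
    ggplot2::facet_wrap(~error_type, ncol = 1) +
    ggplot2::labs(x = "main pollutant / copollutant",
                  y = "copollutant type I error (noisy fit)") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Render the full report bundle from stored scenario results
#'
#' Reads every scenario result CSV in `results_dir`, summarises it, and
#' writes the metrics table, the attenuation and RMSE-ratio tables, and the
#' RR and type-I-error figures into `out_dir`.  The report is a pure
#' function of the result files: re-running it reproduces identical tables.
#'
#' @param results_dir Directory containing `write_scenario_result()` CSVs.
#' @param out_dir Output directory (created if needed).
#' @param two_sided Significance rule for power / type I error.
#' @param figures Also write PDF figures (requires at least one scenario).
#' @return Invisibly, a list with `metrics`, `attenuation`, `rmse_ratios`
#'   and the output paths.
#' @export
report <- function(results_dir, out_dir = results_dir, two_sided = TRUE,
                   figures = TRUE) {
  files <- sort(list.files(results_dir, pattern = "\\.csv$",
                           full.names = TRUE))
  files <- files[!grepl("^(metrics|table_)", basename(files))]
  if (length(files) == 0) {
    stop("no scenario result files in ", results_dir, call. = FALSE)
  }
  results <- lapply(files, read_scenario_result)
  metrics <- summarize_grid(results, two_sided = two_sided)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    metrics = file.path(out_dir, "metrics_table.csv"),
    attenuation = file.path(out_dir, "table_attenuation.csv"),
    rmse = file.path(out_dir, "table_rmse_ratio.csv")
  )
  readr::write_csv(metrics, paths["metrics"])
  att <- attenuation_table(metrics)
  readr::write_csv(att, paths["attenuation"])
  rr <- rmse_ratio_table(metrics)
  readr::write_csv(rr, paths["rmse"])
  if (figures) {
    fig1 <- file.path(out_dir, "fig_rr_estimates.pdf")
    fig2 <- file.path(out_dir, "fig_type1_error.pdf")
    ggplot2::ggsave(fig1, plot_rr_estimates(metrics), width = 9,
                    height = 8)
    ggplot2::ggsave(fig2, plot_type1_error(metrics), width = 9, height = 8)
    paths <- c(paths, fig_rr = fig1, fig_type1 = fig2)
  }
  invisible(list(metrics = metrics, attenuation = att, rmse_ratios = rr,
                 paths = paths))
}
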