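#' Generate daily ZIP-level health-model covariates
#'
#' Produces one record per (zip, day) with the confounders the health model
#' adjusts for: day of week, a holiday flag (a fixed list of ten calendar
#' days per year), per-hospital activity indicators (each hospital
#' contributes over one contiguous random window covering at least half the
#' study), a calendar time index, seasonally varying maximum and minimum
#' temperature (max binned to whole degrees Celsius) and dew point, and a
#' meteorological season label.  Weather and hospital windows are shared
#' across ZIP codes, as in a single-city time series.
#'
#' @param config A [scenario_config()].
#' @param seed Integer seed; output is bit-reproducible given the seed.
#' @return A tibble with columns `zip_id`, `day`, `date`, `day_of_week`,
#'   `holiday`, `hosp_1` ... `hosp_H`, `time`, `max_temp` (integer deg C),
#'   `min_temp`, `dew_point`, `season`.
#' @export
generate_covariates <- function(config, seed = config$seed) {
  validate_scenario(config)
  set.seed(seed + 1L)  # distinct substream from the exposure panel

  nd <- config$n_days
  nh <- config$n_hospitals
  dates <- config$start_date + (seq_len(nd) - 1L)
  doy <- as.integer(format(dates, "%j"))

  # annual cycle peaking mid-July; max temp rounded to whole deg C
  base <- 18 - 11 * cos(2 * pi * (doy - 15) / 365.25)
  max_temp <- round(base + 5 + rnorm(nd, 0, 2.5))
  min_temp <- pmin(base - 5 + rnorm(nd, 0, 2.5), max_temp)
  dew_point <- base - 3 + rnorm(nd, 0, 3)

  month <- as.integer(format(dates, "%m"))
  season <- c("winter", "winter", "spring", "spring", "spring", "summer",
              "summer", "summer", "fall", "fall", "fall", "winter")[month]

  holidays <- c("01-01", "01-18", "05-31", "07-04", "09-06",
                "10-11", "11-11", "11-25", "12-25", "12-31")
  holiday <- format(dates, "%m-%d") %in% holidays

  # contiguous activity window per hospital, >= 50% of the study days
  hosp <- matrix(0L, nd, nh, dimnames = list(NULL, paste0("hosp_", seq_len(nh))))
  for (h in seq_len(nh)) {
    len <- sample(seq.int(ceiling(nd / 2), nd), 1L)
    start <- sample.int(nd - len + 1L, 1L)
    hosp[start:(start + len - 1L), h] <- 1L
  }

  day_tbl <- tibble::tibble(
    day = seq_len(nd), date = dates,
    day_of_week = factor(c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat",
                           "Sun")[as.integer(format(dates, "%u"))],
                         levels = c("Mon", "Tue", "Wed", "Thu", "Fri",
                                    "Sat", "Sun")),
    holiday = holiday, time = seq_len(nd),
    max_temp = as.integer(max_temp), min_temp = min_temp,
    dew_point = dew_point,
    season = factor(season, levels = c("winter", "spring", "summer", "fall"))
  )
  day_tbl <- dplyr::bind_cols(day_tbl, tibble::as_tibble(hosp))

  zip_ids <- sprintf("Z%02d", seq_len(config$n_zips))
  out <- tidyr::expand_grid(zip_id = zip_ids, day = seq_len(nd))
  dplyr::arrange(dplyr::left_join(out, day_tbl, by = "day"),
                 .data$zip_id, .data$day)
}

#' Read or write a covariate table as CSV
#'
#' @param covariates A covariate tibble from [generate_covariates()].
#' @param path File path.
#' @return `read_covariates()` returns the covariate tibble;
#'   `write_covariates()` returns `path` invisibly.
#' @export
write_covariates <- function(covariates, path) {
  readr::write_csv(covariates, path)
  invisible(path)
}

#' @rdname write_covariates
#' @export
read_covariates <- function(path) {
  cov <- readr::read_csv(path, show_col_types = FALSE)
  cov$date <- as.Date(cov$date)
  cov$day_of_week <- factor(cov$day_of_week,
                            levels = c("Mon", "Tue", "Wed", "Thu", "Fri",
                                       "Sat", "Sun"))
  cov$season <- factor(cov$season,
                       levels = c("winter", "spring", "summer", "fall"))
  cov$max_temp <- as.integer(cov$max_temp)
  tibble::as_tibble(cov)
}
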