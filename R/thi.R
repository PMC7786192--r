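#' Temperature-humidity index
#'
#' Computes the THI from daily maximum temperature and mean relative
#' humidity,
#' \deqn{THI = (1.8 T + 32) - (0.55 - 0.0055 H)(1.8 T - 26.8),}
#' the standard livestock heat-stress index on the Fahrenheit-like scale.
#' At `H = 100` the humidity correction vanishes and the index reduces to
#' `1.8 T + 32`; at `T = 26.8 / 1.8` (about 14.89 degrees C) the index is
#' independent of humidity.
#'
#' @param t_max daily maximum temperature, degrees Celsius.
#' @param rh_mean daily mean relative humidity, percent in \[0, 100\].
#' @return THI values, same length as the inputs (recycled).
#' @examples
#' compute_thi(30, 50)
#' compute_thi(25, 100) # == 1.8 * 25 + 32
#' @export
compute_thi <- function(t_max, rh_mean) {
  if (any(!is.finite(rh_mean)) || any(rh_mean < 0 | rh_mean > 100)) {
    stop_mrnm("relative humidity must lie in [0, 100]",
              class = "mrnm_domain_error")
  }
  (1.8 * t_max + 32) - (0.55 - 0.0055 * rh_mean) * (1.8 * t_max - 26.8)
}

#' Average weather over a pre-slaughter window
#'
#' Arithmetic means of daily maximum temperature and mean relative humidity
#' at one station over the inclusive calendar-day window
#' `[slaughter_date - window_start_days, slaughter_date - window_end_days]`.
#' The default window of 15 to 45 days before slaughter targets the last
#' month of the finishing period, excluding the final two weeks of fasting,
#' rest and transport.
#'
#' @param weather data frame with columns `station_id`, `date` (`Date` or
#'   ISO-8601 string), `t_max`, `rh_mean`.
#' @param station station identifier to select.
#' @param slaughter_date slaughter date (`Date` or ISO-8601 string).
#' @param window_start_days,window_end_days inclusive window bounds in days
#'   before slaughter; `window_start_days > window_end_days >= 0`.
#' @return named list with `t_avg`, `h_avg` and `n_days` (records used).
#' @export
window_aggregate <- function(weather, station, slaughter_date,
                             window_start_days = 45, window_end_days = 15) {
  stopifnot(window_start_days > window_end_days, window_end_days >= 0)
  slaughter_date <- as.Date(slaughter_date)
  dates <- as.Date(weather$date)
  lo <- slaughter_date - window_start_days
  hi <- slaughter_date - window_end_days
  sel <- weather$station_id == station & dates >= lo & dates <= hi
  if (!any(sel)) {
    stop_mrnm("no weather records for station '%s' in window [%s, %s]",
              station, format(lo), format(hi),
              class = "mrnm_missing_covariate_error")
  }
  list(t_avg = mean(weather$t_max[sel]),
       h_avg = mean(weather$rh_mean[sel]),
       n_days = sum(sel))
}

# Monthly-mean variant used for the whole-growth-period THI: average
# t_max / rh_mean within each calendar month intersecting the window,
# then average the monthly means.
window_aggregate_monthly <- function(weather, station, slaughter_date,
                                     window_start_days, window_end_days) {
  slaughter_date <- as.Date(slaughter_date)
  dates <- as.Date(weather$date)
  lo <- slaughter_date - window_start_days
  hi <- slaughter_date - window_end_days
  sel <- weather$station_id == station & dates >= lo & dates <= hi
  if (!any(sel)) {
    stop_mrnm("no weather records for station '%s' in window [%s, %s]",
              station, format(lo), format(hi),
              class = "mrnm_missing_covariate_error")
  }
  mon <- format(dates[sel], "%Y-%m")
  list(t_avg = mean(tapply(weather$t_max[sel], mon, mean)),
       h_avg = mean(tapply(weather$rh_mean[sel], mon, mean)),
       n_days = sum(sel))
}

#' Per-animal THI over a pre-slaughter window
#'
#' Computes each animal's raw THI by averaging weather at its mapped
#' station over the window before its slaughter date, then applying
#' [compute_thi()] to the window means, and standardizes the raw values to
#' the covariate `c` (mean 0, population sd 1) over the analysis set.
#'
#' With `whole_period = TRUE` the window spans each animal's whole life
#' (`birth_date` to `slaughter_date - window_end_days`) and weather is
#' averaged month-by-month before averaging across months, emulating a
#' growth-trajectory-wide exposure instead of the finishing period.
#'
#' @param weather weather table as in [window_aggregate()].
#' @param animals data frame with columns `animal_id`, `farm_location`,
#'   `slaughter_date` and (for `whole_period`) `birth_date`.
#' @param station_map optional data frame with columns `farm_location`,
#'   `station_id` linking farms to weather stations; by default the farm
#'   location is used as the station id.
#' @param window_start_days,window_end_days window bounds in days before
#'   slaughter (ignored for `window_start_days` when `whole_period`).
#' @param whole_period logical; use the whole growth period with monthly
#'   averaging.
#' @return data frame with `animal_id`, `t_avg`, `h_avg`, `raw_thi`, `c`.
#' @export
animal_thi <- function(weather, animals, station_map = NULL,
                       window_start_days = 45, window_end_days = 15,
                       whole_period = FALSE) {
  if (is.null(station_map)) {
    station <- as.character(animals$farm_location)
  } else {
    idx <- match(as.character(animals$farm_location),
                 as.character(station_map$farm_location))
    if (anyNA(idx)) {
      bad <- unique(animals$farm_location[is.na(idx)])
      stop_mrnm("no station mapped for farm location(s): %s",
                paste(bad, collapse = ", "), class = "mrnm_lookup_error")
    }
    station <- as.character(station_map$station_id)[idx]
  }
  n <- nrow(animals)
  t_avg <- h_avg <- numeric(n)
  for (i in seq_len(n)) {
    if (whole_period) {
      start_i <- as.integer(as.Date(animals$slaughter_date[i]) -
                              as.Date(animals$birth_date[i]))
      agg <- window_aggregate_monthly(weather, station[i],
                                      animals$slaughter_date[i],
                                      start_i, window_end_days)
    } else {
      agg <- tryCatch(
        window_aggregate(weather, station[i], animals$slaughter_date[i],
                         window_start_days, window_end_days),
        mrnm_missing_covariate_error = function(e) {
          stop_mrnm("animal '%s': %s", animals$animal_id[i],
                    conditionMessage(e),
                    class = "mrnm_missing_covariate_error")
        })
    }
    t_avg[i] <- agg$t_avg
    h_avg[i] <- agg$h_avg
  }
  raw_thi <- compute_thi(t_avg, h_avg)
  data.frame(animal_id = animals$animal_id, t_avg = t_avg, h_avg = h_avg,
             raw_thi = raw_thi, c = standardize_covariate(raw_thi))
}

#' Standardize an environmental covariate
#'
#' Centers and scales to population (divide-by-n) unit variance. Errors on
#' a degenerate (constant) covariate, which cannot carry a reaction norm.
#'
#' @param x numeric vector.
#' @return standardized vector with mean 0 and population sd 1.
#' @export
standardize_covariate <- function(x) {
  s <- pop_sd(x)
  if (!is.finite(s) || s == 0) {
    stop_mrnm("covariate has zero variance; reaction norms on a constant environment are unidentifiable",
              class = "mrnm_degenerate_covariate_error")
  }
  (x - mean(x)) / s
}
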