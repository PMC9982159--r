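# Per-day model inputs: daily aggregation, short lag structure, heat
# adaptation averages, WBGT, hot-day stratification.

# WBGT regression coefficients (temperature-humidity form, no solar term):
# WBGT = c0 + cT*T + cH*RH + cTH*T*RH. Fixed; printed in docs.
.wbgt_coef <- c(c0 = -4.064, cT = 0.735, cH = 0.0374, cTH = 0.00292)

#' Aggregate a weather series to daily mean and maximum temperature
#'
#' @param weather a `weather_series` data frame (`timestamp`, `temp_c`,
#'   `rh_pct`).
#' @return Data frame with columns `date`, `mean_temp`, `max_temp`.
#' @export
daily_aggregate <- function(weather) {
  if (nrow(weather) == 0L) stopf("daily_aggregate: empty weather series")
  day <- factor(as.Date(weather$timestamp, tz = "UTC"))
  data.frame(
    date = as.Date(levels(day)),
    mean_temp = as.numeric(tapply(weather$temp_c, day, mean)),
    max_temp = as.numeric(tapply(weather$temp_c, day, max)),
    row.names = NULL
  )
}

#' Three-day weighted input for the indoor equation
#'
#' Weighted combination `0.6 x_t + 0.2 x_(t-1) + 0.2 x_(t-2)` of a per-day
#' input series; the short lag structure of indoor (non-exertional) cases.
#'
#' @param x numeric per-day series (one season, consecutive days).
#' @return Numeric vector of the same length; the first two entries are `NA`
#'   (insufficient history).
#' @export
indoor_lag_input <- function(x) {
  n <- length(x)
  if (n < 3L) stopf("indoor_lag_input: need at least 3 days of history")
  out <- rep(NA_real_, n)
  idx <- 3:n
  out[idx] <- 0.6 * x[idx] + 0.2 * x[idx - 1L] + 0.2 * x[idx - 2L]
  out
}

#' Configuration of the heat-adaptation window
#'
#' @param J window length in days (>= 1).
#' @param weight_shape `"linear_decreasing"` (most recent day heaviest,
#'   weights `2(J-i+1)/(J(J+1))` for lag `i = 1..J`) or `"uniform"`.
#' @return An object of class `adaptation_config`.
#' @export
adaptation_config <- function(J, weight_shape = c("linear_decreasing", "uniform")) {
  weight_shape <- match.arg(weight_shape)
  if (!is.numeric(J) || length(J) != 1L || J < 1 || J != round(J)) {
    stopf("adaptation_config: J must be an integer >= 1")
  }
  structure(list(J = as.integer(J), weight_shape = weight_shape),
            class = "adaptation_config")
}

#' Adaptation-window weights
#'
#' @param cfg an [adaptation_config()].
#' @return Positive weights over lags `1..J`, summing to 1.
#' @export
adaptation_weights <- function(cfg) {
  J <- cfg$J
  w <- switch(cfg$weight_shape,
              linear_decreasing = 2 * (J - seq_len(J) + 1) / (J * (J + 1)),
              uniform = rep(1 / J, J))
  w
}

#' Weighted moving average over the previous J days
#'
#' Heat-acclimatization average `sum_{i=1..J} w_i x_(t-i)`: the current day
#' is excluded (lags start at 1).
#'
#' @param x numeric per-day series (one season, consecutive days).
#' @param cfg an [adaptation_config()].
#' @return Numeric vector of the same length; entries with fewer than `J`
#'   preceding days are `NA`.
#' @export
adaptation_average <- function(x, cfg) {
  J <- cfg$J
  n <- length(x)
  if (n <= J) stopf("adaptation_average: series of length %d cannot supply J = %d lagged days", n, J)
  w <- adaptation_weights(cfg)
  out <- rep(NA_real_, n)
  for (t in (J + 1L):n) out[t] <- sum(w * x[t - seq_len(J)])
  out
}

#' Wet-bulb globe temperature from temperature and humidity
#'
#' Regression approximation without a solar-radiation term:
#' `WBGT = -4.064 + 0.735 T + 0.0374 RH + 0.00292 T RH` (T in degC, RH in
#' percent). Monotone nondecreasing in both arguments over the summer range.
#' Used only to stratify hot days, so approximation error merely shifts the
#' stratum boundary.
#'
#' @param temp ambient temperature, degC.
#' @param rh relative humidity, percent, in `[0, 100]`.
#' @return WBGT, degC (vectorized).
#' @export
compute_wbgt <- function(temp, rh) {
  if (any(is.na(rh)) || any(rh < 0 | rh > 100)) {
    stopf("compute_wbgt: rh must be in [0, 100]")
  }
  b <- .wbgt_coef
  b[["c0"]] + b[["cT"]] * temp + b[["cH"]] * rh + b[["cTH"]] * temp * rh
}

#' Dates whose WBGT reaches a hot-day threshold
#'
#' @param exposure an `exposure_series` (see [build_exposure()]).
#' @param threshold WBGT threshold, degC (default 31, the hot-day criterion).
#' @return Vector of dates with `wbgt >= threshold`.
#' @export
hot_day_mask <- function(exposure, threshold = 31) {
  if (!"wbgt" %in% names(exposure) || all(is.na(exposure$wbgt))) {
    stopf("hot_day_mask: exposure has no populated wbgt column")
  }
  exposure$date[!is.na(exposure$wbgt) & exposure$wbgt >= threshold]
}

#' Build the per-day exposure series
#'
#' Combines daily temperature aggregates, daily WBGT (maximum over the
#' day's hourly WBGT values) and, when supplied, the thermophysiological
#' daily summaries into the exposure table consumed by the risk model.
#'
#' @param weather a `weather_series`.
#' @param thermo optional `thermo_daily` from [simulate_season()].
#' @return Data frame of class `exposure_series` with columns `date`,
#'   `season` (calendar year), `mean_temp`, `max_temp`,
#'   `peak_core_increase`, `total_sweat`, `wbgt`.
#' @export
build_exposure <- function(weather, thermo = NULL) {
  agg <- daily_aggregate(weather)
  day <- factor(as.Date(weather$timestamp, tz = "UTC"))
  wbgt_h <- compute_wbgt(weather$temp_c, weather$rh_pct)
  agg$wbgt <- as.numeric(tapply(wbgt_h, day, max))
  agg$season <- as.integer(format(agg$date, "%Y"))
  agg$peak_core_increase <- NA_real_
  agg$total_sweat <- NA_real_
  if (!is.null(thermo)) {
    m <- match(agg$date, thermo$date)
    agg$peak_core_increase <- thermo$peak_core_increase_c[m]
    agg$total_sweat <- thermo$total_sweat_g[m]
  }
  out <- agg[, c("date", "season", "mean_temp", "max_temp",
                 "peak_core_increase", "total_sweat", "wbgt")]
  if (any(diff(out$date) <= 0)) stopf("build_exposure: dates must be strictly increasing")
  structure(out, class = c("exposure_series", "data.frame"))
}

# Column of an exposure series holding a given model input kind.
exposure_input <- function(exposure, input_kind) {
  col <- switch(input_kind,
                average_temperature = "mean_temp",
                sweating = "total_sweat",
                core_temperature_increase = "peak_core_increase",
                stopf("unknown input_kind '%s'", input_kind))
  x <- exposure[[col]]
  if (all(is.na(x))) {
    stopf("exposure series has no data for input kind '%s'", input_kind)
  }
  x
}
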