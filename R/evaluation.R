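# Scoring of estimates against observed counts: coefficient of
# determination, MAE per million population, F-tests, seasonal error
# profiles and the hot-day stratification.

#' Coefficient of determination
#'
#' `R^2 = 1 - SS_res / SS_tot`, computed directly (not squared Pearson
#' correlation), so it is meaningful for held-out predictions.
#'
#' @param observed,estimated numeric vectors of equal length (>= 2).
#' @return R^2 (can be negative for predictions worse than the mean).
#' @export
r_squared <- function(observed, estimated) {
  if (length(observed) != length(estimated) || length(observed) < 2L) {
    stopf("r_squared: need equal-length vectors with >= 2 elements")
  }
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot <= 0) stopf("r_squared: observed series is constant, R^2 undefined")
  1 - sum((observed - estimated)^2) / ss_tot
}

#' Mean absolute error per million population
#'
#' @param observed,estimated daily counts.
#' @param population population of the region, persons.
#' @return `mean(|observed - estimated|) * 1e6 / population`.
#' @export
mae_per_million <- function(observed, estimated, population) {
  if (population <= 0) stopf("mae_per_million: population must be positive")
  mean(abs(observed - estimated)) * 1e6 / population
}

#' Overall-regression F-test
#'
#' Tests the fitted model against the intercept-only model:
#' `F = ((SS_tot - SS_res)/p) / (SS_res/(n - p - 1))` with
#' `p = n_params` actually-fitted parameters; the p-value comes from the
#' `F(p, n - p - 1)` distribution. Significance is conventionally assessed
#' at p < 0.05.
#'
#' @param observed,estimated numeric vectors.
#' @param n_params number of fitted parameters of the estimating equation
#'   (4 for temperature inputs; fewer for thermophysiological inputs).
#' @return List with `statistic`, `df1`, `df2`, `p_value`.
#' @export
f_test <- function(observed, estimated, n_params) {
  n <- length(observed)
  if (n <= n_params + 1L) stopf("f_test: need n > n_params + 1")
  ss_tot <- sum((observed - mean(observed))^2)
  ss_res <- sum((observed - estimated)^2)
  if (ss_tot <= 0) stopf("f_test: observed series is constant")
  df1 <- n_params
  df2 <- n - n_params - 1L
  stat <- ((ss_tot - ss_res) / df1) / (ss_res / df2)
  list(statistic = stat, df1 = df1, df2 = df2,
       p_value = pf(stat, df1, df2, lower.tail = FALSE))
}

#' Seasonal MAE profile
#'
#' MAE per million population within consecutive day-of-season bins
#' (default 10-day), with the across-year standard deviation per bin.
#'
#' @param observed,estimated daily counts.
#' @param dates dates of the days.
#' @param population population, persons.
#' @param bin bin width in days (default 10).
#' @param season_start month-day string defining day-of-season 1.
#' @return Data frame with `bin_start` (day-of-season), `mae`, `sd`,
#'   `n_days`.
#' @export
seasonal_mae_profile <- function(observed, estimated, dates, population,
                                 bin = 10, season_start = "06-01") {
  if (bin < 1) stopf("seasonal_mae_profile: bin must be >= 1")
  year <- as.integer(format(dates, "%Y"))
  start <- as.Date(paste0(year, "-", season_start))
  dos <- as.integer(dates - start) + 1L
  bin_id <- (dos - 1L) %/% bin
  err <- abs(observed - estimated) * 1e6 / population
  cell <- aggregate(err, by = list(bin = bin_id, year = year), FUN = mean)
  prof <- aggregate(cell$x, by = list(bin = cell$bin),
                    FUN = function(v) c(mae = mean(v), sd = if (length(v) > 1) sd(v) else 0))
  nd <- aggregate(rep(1L, length(bin_id)), by = list(bin = bin_id), FUN = sum)
  data.frame(bin_start = prof$bin * bin + 1L,
             mae = prof$x[, "mae"], sd = prof$x[, "sd"],
             n_days = nd$x)
}

#' Errors on hot days (WBGT at or above a threshold)
#'
#' Restricts the comparison to dates whose WBGT reaches the threshold and
#' reports signed per-day differences (observed minus estimated, per
#' million population), their MAE, and the number of hot days.
#'
#' @param observed,estimated daily counts.
#' @param dates dates of the days.
#' @param population population, persons.
#' @param exposure an `exposure_series` with populated `wbgt`.
#' @param threshold WBGT threshold, degC (default 31).
#' @return List with `differences` (data frame `date`, `diff_per_million`),
#'   `mae` (`NA` when no hot days), `n_days`.
#' @export
hot_day_errors <- function(observed, estimated, dates, population, exposure,
                           threshold = 31) {
  hot <- hot_day_mask(exposure, threshold)
  sel <- dates %in% hot
  n <- sum(sel)
  diffs <- data.frame(
    date = dates[sel],
    diff_per_million = (observed[sel] - estimated[sel]) * 1e6 / population
  )
  list(differences = diffs,
       mae = if (n > 0) mean(abs(diffs$diff_per_million)) else NA_real_,
       n_days = n)
}

#' Full evaluation report for a cross-validated fit
#'
#' Scores the held-out predictions of a [loocv_by_year()] result: R^2 and
#' MAE per million for all/indoor/outdoor, F-test p-values per equation,
#' the seasonal MAE profile and the hot-day stratum.
#'
#' @param fit a `fit_result` from [loocv_by_year()].
#' @param exposure the `exposure_series` used for fitting.
#' @param population population, persons.
#' @param bin seasonal profile bin width, days.
#' @param threshold hot-day WBGT threshold, degC.
#' @return List of class `evaluation_report`.
#' @export
evaluate_fit <- function(fit, exposure, population, bin = 10, threshold = 31) {
  pr <- fit$predictions
  n_par <- function(cfg) {
    2L + (cfg$l_policy == "free") + (cfg$f_policy == "free")
  }
  cfg_in <- fit$per_year[[1]]$fit_indoor$cfg
  cfg_out <- fit$per_year[[1]]$fit_outdoor$cfg
  rep <- list(
    r2 = c(all = r_squared(pr$obs_total, pr$y),
           indoor = r_squared(pr$obs_indoor, pr$y_in),
           outdoor = r_squared(pr$obs_outdoor, pr$y_out)),
    mae_per_million = c(
      all = mae_per_million(pr$obs_total, pr$y, population),
      indoor = mae_per_million(pr$obs_indoor, pr$y_in, population),
      outdoor = mae_per_million(pr$obs_outdoor, pr$y_out, population)),
    f_test = list(
      indoor = f_test(pr$obs_indoor, pr$y_in, n_par(cfg_in)),
      outdoor = f_test(pr$obs_outdoor, pr$y_out, n_par(cfg_out))),
    seasonal_profile = seasonal_mae_profile(pr$obs_total, pr$y, pr$date,
                                            population, bin = bin),
    hot_days = hot_day_errors(pr$obs_total, pr$y, pr$date, population,
                              exposure, threshold = threshold)
  )
  structure(rep, class = "evaluation_report")
}
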