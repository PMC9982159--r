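# Seeded generators for multi-year summer weather, prefecture-like age
# pyramids, and Poisson daily patient counts whose mean follows the
# morbidity model. The stated world for all downstream testing.

#' Weather scenario
#'
#' Describes a multi-year synthetic summer weather regime: a seasonal
#' half-sine over each June 1 - September 30 season, a rainy-season cooling
#' applied before the rainy-season end (around July 20), AR(1) day-to-day
#' variability, a diurnal cycle peaking at 14:00, and relative humidity
#' anticorrelated with temperature.
#'
#' @param n_years number of seasons.
#' @param first_year calendar year of the first season.
#' @param season_start,season_end month-day strings (default June 1 and
#'   September 30).
#' @param base_temp season-edge daily-mean temperature, degC.
#' @param seasonal_amplitude half-sine amplitude of the daily mean, degC.
#' @param diurnal_amplitude amplitude of the within-day cosine, degC.
#' @param rainy_season_end day-of-season index before which the rainy-season
#'   cooling applies (day 50 of a June 1 start is about July 20).
#' @param rainy_season_cooling cooling applied before the rainy-season end,
#'   degC.
#' @param ar1_coef AR(1) coefficient of daily anomalies, in `[0, 1)`.
#' @param noise_sd AR(1) innovation standard deviation, degC (>= 0).
#' @param rh_base relative humidity at `base_temp`, percent.
#' @param rh_temp_slope humidity decrease per degC above `base_temp`, %/degC.
#' @param rh_noise_sd humidity noise standard deviation, percent.
#' @param seed RNG seed.
#' @return An object of class `weather_scenario`.
#' @export
weather_scenario <- function(n_years = 7, first_year = 2013,
                             season_start = "06-01", season_end = "09-30",
                             base_temp = 24, seasonal_amplitude = 6,
                             diurnal_amplitude = 4,
                             rainy_season_end = 50, rainy_season_cooling = 2,
                             ar1_coef = 0.6, noise_sd = 1.5,
                             rh_base = 80, rh_temp_slope = 1.5,
                             rh_noise_sd = 3, seed = 1L) {
  if (n_years < 1 || n_years != round(n_years)) {
    stopf("weather_scenario: n_years must be a positive integer")
  }
  if (ar1_coef < 0 || ar1_coef >= 1) stopf("weather_scenario: ar1_coef must be in [0, 1)")
  if (noise_sd < 0) stopf("weather_scenario: noise_sd must be >= 0")
  d0 <- as.Date(paste0(first_year, "-", season_start))
  d1 <- as.Date(paste0(first_year, "-", season_end))
  if (is.na(d0) || is.na(d1) || d1 <= d0) {
    stopf("weather_scenario: season end must follow season start")
  }
  structure(list(n_years = as.integer(n_years), first_year = as.integer(first_year),
                 season_start = season_start, season_end = season_end,
                 base_temp = base_temp, seasonal_amplitude = seasonal_amplitude,
                 diurnal_amplitude = diurnal_amplitude,
                 rainy_season_end = rainy_season_end,
                 rainy_season_cooling = rainy_season_cooling,
                 ar1_coef = ar1_coef, noise_sd = noise_sd,
                 rh_base = rh_base, rh_temp_slope = rh_temp_slope,
                 rh_noise_sd = rh_noise_sd, seed = seed),
            class = "weather_scenario")
}

#' Deterministic seasonal daily-mean curve
#'
#' The closed-form daily-mean temperature of a scenario with all noise
#' switched off: base + seasonal half-sine, minus the rainy-season cooling
#' before the rainy-season end. Serves as the analytic reference for
#' Monte-Carlo checks of [generate_weather()].
#'
#' @param scenario a [weather_scenario()].
#' @return Numeric vector over the days of one season.
#' @export
seasonal_daily_mean <- function(scenario) {
  d0 <- as.Date(paste0(scenario$first_year, "-", scenario$season_start))
  d1 <- as.Date(paste0(scenario$first_year, "-", scenario$season_end))
  nd <- as.integer(d1 - d0) + 1L
  d <- seq_len(nd)
  m <- scenario$base_temp +
    scenario$seasonal_amplitude * sin(pi * (d - 1) / (nd - 1))
  m[d < scenario$rainy_season_end] <- m[d < scenario$rainy_season_end] -
    scenario$rainy_season_cooling
  m
}

#' Generate a multi-year hourly weather series
#'
#' @param scenario a [weather_scenario()].
#' @return Data frame of class `weather_series` with hourly `timestamp`
#'   (UTC), `temp_c` and `rh_pct` over every season. Humidity is clipped to
#'   `[5, 100]`. Identical seeds give bit-identical output.
#' @export
generate_weather <- function(scenario = weather_scenario()) {
  stopifnot(inherits(scenario, "weather_scenario"))
  det_mean <- seasonal_daily_mean(scenario)
  nd <- length(det_mean)
  hours <- 0:23
  diurnal <- scenario$diurnal_amplitude * cos(2 * pi * (hours - 14) / 24)
  with_seed(scenario$seed, {
    out <- vector("list", scenario$n_years)
    for (yidx in seq_len(scenario$n_years)) {
      year <- scenario$first_year + yidx - 1L
      d0 <- as.Date(paste0(year, "-", scenario$season_start))
      dates <- d0 + 0:(nd - 1L)
      # AR(1) daily anomaly, stationary start
      eps <- rnorm(nd, 0, scenario$noise_sd)
      anom <- numeric(nd)
      anom[1] <- if (scenario$ar1_coef > 0 && scenario$noise_sd > 0) {
        rnorm(1, 0, scenario$noise_sd / sqrt(1 - scenario$ar1_coef^2))
      } else eps[1]
      for (d in 2:nd) anom[d] <- scenario$ar1_coef * anom[d - 1] + eps[d]
      if (scenario$noise_sd == 0) anom[] <- 0
      daily <- det_mean + anom
      temp <- rep(daily, each = 24) + rep(diurnal, nd)
      rh <- scenario$rh_base -
        scenario$rh_temp_slope * (temp - scenario$base_temp) +
        rnorm(length(temp), 0, scenario$rh_noise_sd)
      out[[yidx]] <- data.frame(
        timestamp = as.POSIXct(paste(rep(dates, each = 24),
                                     sprintf("%02d:00:00", rep(hours, nd))),
                               tz = "UTC"),
        temp_c = temp,
        rh_pct = clip(rh, 5, 100)
      )
    }
    structure(do.call(rbind, out),
              class = c("weather_series", "data.frame"))
  })
}

#' Generate an age composition
#'
#' Softmax-shaped pyramid over the 14 adult 5-year categories:
#' `P(n) proportional to exp(aging_index * n / 14)`. `aging_index = 0` gives
#' the flat pyramid; larger values shift mass toward older categories.
#'
#' @param aging_index nonnegative shape parameter (default 2, an aged
#'   prefecture-like pyramid).
#' @return An object of class `age_composition`: 14 named fractions
#'   summing to 1.
#' @export
generate_age_composition <- function(aging_index = 2) {
  if (!is.numeric(aging_index) || length(aging_index) != 1L || aging_index < 0) {
    stopf("generate_age_composition: aging_index must be >= 0")
  }
  w <- exp(aging_index * (1:14) / 14)
  p <- w / sum(w)
  structure(setNames(p, paste0("n", 1:14)), class = "age_composition")
}

#' Default generating parameter sets
#'
#' Parameter magnitudes patterned on a large humid-subtropical metropolitan
#' prefecture, one set per input kind. Temperature inputs use the four-
#' parameter form (free `l`, `f`); thermophysiological inputs pin `l = -1`,
#' and the outdoor class drops `f` (no adaptation slope). Windows default to
#' the plateau values J = 40 (indoor) and J = 30 (outdoor).
#'
#' @param input_kind model input kind.
#' @return A [risk_parameters()] object.
#' @export
default_parameters <- function(input_kind = c("average_temperature", "sweating",
                                              "core_temperature_increase")) {
  input_kind <- match.arg(input_kind)
  switch(input_kind,
    average_temperature = risk_parameters(
      indoor = risk_class_params(a = 4.5e-7, l = -2.33e4, f = -6.97e-3,
                                 g = 0.631, input_kind = input_kind, J = 40),
      outdoor = risk_class_params(a = 3.3e-6, l = -3.92e3, f = -5.86e-3,
                                  g = 0.519, input_kind = input_kind, J = 30)
    ),
    sweating = risk_parameters(
      indoor = risk_class_params(a = 0.08, l = -1, f = -1e-6, g = 1.5e-3,
                                 input_kind = input_kind, J = 40),
      outdoor = risk_class_params(a = 0.05, l = -1, f = NA, g = 1e-3,
                                  input_kind = input_kind, J = 30)
    ),
    core_temperature_increase = risk_parameters(
      indoor = risk_class_params(a = 0.1, l = -1, f = -5.22, g = 5.28,
                                 input_kind = input_kind, J = 20),
      outdoor = risk_class_params(a = 0.25, l = -1, f = NA, g = 3.21,
                                  input_kind = input_kind, J = 20)
    )
  )
}

#' Generating-model specification
#'
#' The "true model" used to synthesize daily counts: a full parameter set
#' plus a count noise model.
#'
#' @param params a [risk_parameters()] (default:
#'   `default_parameters("average_temperature")`).
#' @param noise `"poisson"` (counts drawn from Poisson with the model mean)
#'   or `"none"` (real-valued model means emitted as counts).
#' @param population prefecture population, persons (carried through to
#'   per-million error metrics).
#' @return An object of class `true_model_spec`.
#' @export
true_model_spec <- function(params = default_parameters(),
                            noise = c("poisson", "none"),
                            population = 1e7) {
  noise <- match.arg(noise)
  stopifnot(inherits(params, "risk_parameters"))
  if (population <= 0) stopf("true_model_spec: population must be positive")
  structure(list(params = params, noise = noise, population = population),
            class = "true_model_spec")
}

#' Generate daily patient counts from an exposure series
#'
#' Evaluates the morbidity model of the generating specification and, under
#' Poisson noise, draws independent indoor and outdoor counts with the model
#' means; `total = indoor + outdoor` always.
#'
#' @param exposure an `exposure_series` long enough to supply the lag and
#'   adaptation history before the first emitted day.
#' @param pop an `age_composition`.
#' @param spec a [true_model_spec()].
#' @param seed RNG seed for the count draws.
#' @return Data frame of class `daily_counts` with columns `date`, `season`,
#'   `indoor`, `outdoor`, `total`, `population`.
#' @export
generate_patient_counts <- function(exposure, pop, spec = true_model_spec(),
                                    seed = 1L) {
  stopifnot(inherits(spec, "true_model_spec"))
  est <- estimate_series(exposure, pop, spec$params)
  if (spec$noise == "poisson") {
    counts <- with_seed(seed, {
      data.frame(indoor = rpois(nrow(est), est$y_in),
                 outdoor = rpois(nrow(est), est$y_out))
    })
  } else {
    counts <- data.frame(indoor = est$y_in, outdoor = est$y_out)
  }
  structure(data.frame(date = est$date, season = est$season,
                       indoor = counts$indoor, outdoor = counts$outdoor,
                       total = counts$indoor + counts$outdoor,
                       population = spec$population),
            class = c("daily_counts", "data.frame"))
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper: weather, thermophysiology (only when the generating
#' model needs it), exposure features, age composition and daily counts.
#'
#' @param scenario a [weather_scenario()].
#' @param spec a [true_model_spec()].
#' @param aging_index age-pyramid shape for [generate_age_composition()].
#' @param subject a [subject_model()] (used only for thermophysiological
#'   input kinds).
#' @param dt thermophysiology integration step, seconds.
#' @param count_seed RNG seed for the count draws (default: scenario seed).
#' @return List with elements `weather`, `thermo` (or `NULL`), `exposure`,
#'   `pop`, `counts`, `spec`.
#' @export
generate_dataset <- function(scenario = weather_scenario(),
                             spec = true_model_spec(),
                             aging_index = 2,
                             subject = subject_model(), dt = 60,
                             count_seed = scenario$seed) {
  weather <- generate_weather(scenario)
  kinds <- c(spec$params$indoor$input_kind, spec$params$outdoor$input_kind)
  thermo <- NULL
  if (any(kinds != "average_temperature")) {
    thermo <- simulate_season(weather, subject, dt = dt)
  }
  exposure <- build_exposure(weather, thermo)
  pop <- generate_age_composition(aging_index)
  counts <- generate_patient_counts(exposure, pop, spec, seed = count_seed)
  list(weather = weather, thermo = thermo, exposure = exposure,
       pop = pop, counts = counts, spec = spec)
}
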