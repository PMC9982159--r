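# Shared fixtures, lazily computed once per test session. The seven-season
# thermophysiology run is the expensive one (~1 min); everything that needs
# it shares the cache.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache, inherits = FALSE)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

fix_weather7 <- function() {
  fixture("weather7", function() generate_weather(weather_scenario(seed = 1)))
}

fix_exposure_temp <- function() {
  fixture("exposure_temp", function() build_exposure(fix_weather7()))
}

fix_thermo7 <- function() {
  fixture("thermo7", function() simulate_season(fix_weather7()))
}

fix_exposure_thermo <- function() {
  fixture("exposure_thermo", function() build_exposure(fix_weather7(), fix_thermo7()))
}

fix_pop <- function() generate_age_composition(2)

# One hot-summer season and its +2 degC shifted twin (criteria 5 and 6).
fix_season1 <- function() {
  fixture("season1", function() {
    w <- generate_weather(weather_scenario(n_years = 1, seed = 3))
    w2 <- w
    w2$temp_c <- w2$temp_c + 2
    list(weather = w, daily = simulate_season(w), daily_plus2 = simulate_season(w2))
  })
}

# Constant-condition weather block (one contiguous "season").
const_weather <- function(temp, rh, days = 3, start = "2019-07-01") {
  ts <- seq(as.POSIXct(paste(start, "00:00:00"), tz = "UTC"),
            by = 3600, length.out = days * 24)
  structure(data.frame(timestamp = ts, temp_c = temp, rh_pct = rh),
            class = c("weather_series", "data.frame"))
}

# Hand-built exposure series (one season unless dates say otherwise).
make_exposure <- function(dates, mean_temp, max_temp = mean_temp,
                          core = NA_real_, sweat = NA_real_, wbgt = NA_real_) {
  structure(data.frame(date = dates,
                       season = as.integer(format(dates, "%Y")),
                       mean_temp = mean_temp, max_temp = max_temp,
                       peak_core_increase = core, total_sweat = sweat,
                       wbgt = wbgt),
            class = c("exposure_series", "data.frame"))
}
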