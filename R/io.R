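# CSV readers/writers, the flat parameter file, and the historical
# indoor/outdoor split utility. All files are UTF-8 CSV with a header,
# dates ISO-8601, one row per day (or per hour for weather).

read_validated_csv <- function(path, required) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss) > 0) {
    stopf("%s: missing required columns: %s", path, paste(miss, collapse = ", "))
  }
  df
}

parse_dates <- function(x, path, col) {
  d <- as.Date(x, format = "%Y-%m-%d")
  bad <- which(is.na(d))
  if (length(bad) > 0) {
    stopf("%s: unparseable %s at line %d (value '%s')",
          path, col, bad[1] + 1L, x[bad[1]])
  }
  d
}

#' Read an hourly weather CSV
#'
#' Columns: `timestamp` (ISO-8601), `temp_c`, `rh_pct`.
#'
#' @param path file path.
#' @return A `weather_series` data frame sorted by timestamp.
#' @export
read_weather <- function(path) {
  df <- read_validated_csv(path, c("timestamp", "temp_c", "rh_pct"))
  ts <- as.POSIXct(strptime(df$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC"))
  alt <- is.na(ts)
  ts[alt] <- as.POSIXct(strptime(df$timestamp[alt], "%Y-%m-%d %H:%M:%S", tz = "UTC"))
  bad <- which(is.na(ts))
  if (length(bad) > 0) {
    stopf("%s: unparseable timestamp at line %d (value '%s')",
          path, bad[1] + 1L, df$timestamp[bad[1]])
  }
  bad_rh <- which(is.na(df$rh_pct) | df$rh_pct < 0 | df$rh_pct > 100)
  if (length(bad_rh) > 0) {
    stopf("%s: rh_pct outside [0, 100] at line %d", path, bad_rh[1] + 1L)
  }
  out <- data.frame(timestamp = ts, temp_c = as.numeric(df$temp_c),
                    rh_pct = as.numeric(df$rh_pct))
  out <- out[order(out$timestamp), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("weather_series", "data.frame"))
}

#' Write an hourly weather CSV
#' @param weather a `weather_series`.
#' @param path file path.
#' @export
write_weather <- function(weather, path) {
  df <- data.frame(timestamp = format(weather$timestamp, "%Y-%m-%dT%H:%M:%S"),
                   temp_c = weather$temp_c, rh_pct = weather$rh_pct)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an age-composition CSV
#'
#' Columns: `category` (1..14), `fraction`. Fractions must be nonnegative
#' and sum to 1 within 1e-6.
#'
#' @param path file path.
#' @return An `age_composition`.
#' @export
read_population <- function(path) {
  df <- read_validated_csv(path, c("category", "fraction"))
  if (!identical(sort(as.integer(df$category)), 1:14)) {
    stopf("%s: categories must be exactly 1..14", path)
  }
  p <- df$fraction[order(df$category)]
  if (any(p < 0)) stopf("%s: negative fraction", path)
  if (abs(sum(p) - 1) > 1e-6) stopf("%s: fractions sum to %.8f, not 1", path, sum(p))
  structure(setNames(as.numeric(p), paste0("n", 1:14)), class = "age_composition")
}

#' Write an age-composition CSV
#' @param pop an `age_composition`.
#' @param path file path.
#' @export
write_population <- function(pop, path) {
  write.csv(data.frame(category = 1:14, fraction = as.numeric(pop)),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a daily patient-counts CSV
#'
#' Columns: `date`, `indoor`, `outdoor`, `total`, `population`. Enforces
#' nonnegative counts and `total = indoor + outdoor` row by row.
#'
#' @param path file path.
#' @return A `daily_counts` data frame sorted by date (with a `season`
#'   column derived from the calendar year).
#' @export
read_counts <- function(path) {
  df <- read_validated_csv(path, c("date", "indoor", "outdoor", "total", "population"))
  d <- parse_dates(df$date, path, "date")
  neg <- which(df$indoor < 0 | df$outdoor < 0 | df$total < 0)
  if (length(neg) > 0) stopf("%s: negative count at line %d", path, neg[1] + 1L)
  bad <- which(abs(df$total - (df$indoor + df$outdoor)) > 1e-9)
  if (length(bad) > 0) {
    stopf("%s: total != indoor + outdoor at line %d", path, bad[1] + 1L)
  }
  out <- data.frame(date = d, season = as.integer(format(d, "%Y")),
                    indoor = df$indoor, outdoor = df$outdoor,
                    total = df$total, population = df$population)
  out <- out[order(out$date), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("daily_counts", "data.frame"))
}

#' Write a daily patient-counts CSV
#' @param counts a `daily_counts` data frame.
#' @param path file path.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(date = format(counts$date, "%Y-%m-%d"),
                   indoor = counts$indoor, outdoor = counts$outdoor,
                   total = counts$total, population = counts$population)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an exposure CSV
#' @param exposure an `exposure_series`.
#' @param path file path.
#' @export
write_exposure <- function(exposure, path) {
  df <- data.frame(date = format(exposure$date, "%Y-%m-%d"),
                   mean_temp_c = exposure$mean_temp,
                   max_temp_c = exposure$max_temp,
                   peak_core_increase_c = exposure$peak_core_increase,
                   total_sweat_g = exposure$total_sweat,
                   wbgt_c = exposure$wbgt)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an exposure CSV
#' @param path file path.
#' @return An `exposure_series`.
#' @export
read_exposure <- function(path) {
  df <- read_validated_csv(path, c("date", "mean_temp_c", "max_temp_c", "wbgt_c"))
  d <- parse_dates(df$date, path, "date")
  out <- data.frame(date = d, season = as.integer(format(d, "%Y")),
                    mean_temp = df$mean_temp_c, max_temp = df$max_temp_c,
                    peak_core_increase = if ("peak_core_increase_c" %in% names(df))
                      df$peak_core_increase_c else NA_real_,
                    total_sweat = if ("total_sweat_g" %in% names(df))
                      df$total_sweat_g else NA_real_,
                    wbgt = df$wbgt_c)
  out <- out[order(out$date), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("exposure_series", "data.frame"))
}

#' Write a flat key-value parameter file
#'
#' One block per location class, keys `<class>.<name>`, mirroring the
#' published per-class layout. Absent `f` is written as `NA`.
#'
#' @param params a [risk_parameters()].
#' @param path file path.
#' @export
write_parameters <- function(params, path) {
  lines <- character(0)
  for (cls in c("indoor", "outdoor")) {
    p <- params[[cls]]
    lines <- c(lines,
               sprintf("%s.input_kind = %s", cls, p$input_kind),
               sprintf("%s.a = %.17g", cls, p$a),
               sprintf("%s.l = %.17g", cls, p$l),
               sprintf("%s.f = %s", cls, if (is.na(p$f)) "NA" else sprintf("%.17g", p$f)),
               sprintf("%s.g = %.17g", cls, p$g),
               sprintf("%s.J = %d", cls, p$adaptation$J),
               sprintf("%s.weight_shape = %s", cls, p$adaptation$weight_shape))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a flat key-value parameter file
#' @param path file path.
#' @return A [risk_parameters()].
#' @export
read_parameters <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[`, character(1), 1L)
  vals <- vapply(kv, `[`, character(1), 2L)
  get1 <- function(cls, name) {
    v <- vals[keys == paste0(cls, ".", name)]
    if (length(v) != 1L) stopf("%s: missing key %s.%s", path, cls, name)
    v
  }
  mk <- function(cls) {
    fv <- get1(cls, "f")
    risk_class_params(a = as.numeric(get1(cls, "a")),
                      l = as.numeric(get1(cls, "l")),
                      f = if (identical(fv, "NA")) NA_real_ else as.numeric(fv),
                      g = as.numeric(get1(cls, "g")),
                      input_kind = get1(cls, "input_kind"),
                      J = as.integer(get1(cls, "J")),
                      weight_shape = get1(cls, "weight_shape"))
  }
  risk_parameters(mk("indoor"), mk("outdoor"))
}

#' Split historical totals into indoor and outdoor counts
#'
#' Applies a mean indoor share to years whose counts were not classified by
#' occurrence location. The split is real-valued; rounding is left to
#' display.
#'
#' @param total total daily counts (vectorized).
#' @param indoor_fraction mean indoor share, in `[0, 1]`.
#' @return List with `indoor = total * indoor_fraction` and
#'   `outdoor = total - indoor` (the split conserves the total exactly).
#' @export
split_total_by_location <- function(total, indoor_fraction) {
  if (any(indoor_fraction < 0 | indoor_fraction > 1)) {
    stopf("split_total_by_location: indoor_fraction must be in [0, 1]")
  }
  indoor <- total * indoor_fraction
  list(indoor = indoor, outdoor = total - indoor)
}
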