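# Nonlinear indoor/outdoor morbidity model: daily expected transported
# patients y = y_in + y_out with
#   y_in  = a_in  * (exp(k_in * (0.6 x0 + 0.2 x1 + 0.2 x2)) + l_in) * S(P)
#   y_out = a_out * (exp(k_out * x0) + l_out) * S(P)
#   k     = f * (J-day weighted average of past input) + g
#   S(P)  = sum_n P(n) * (b e^(c n) + d), the age-weighted population risk.

#' Age-risk regression constants
#'
#' Constants of the age-risk curve `b e^(c n) + d` over the 14 adult 5-year
#' age categories (n = 1: 20-24 years, ..., n = 14: 85+).
#'
#' @param b,c,d regression constants; defaults 0.171, 0.494 and 190.7.
#' @return An object of class `age_risk_constants`.
#' @export
age_risk_constants <- function(b = 0.171, c = 0.494, d = 190.7) {
  if (b < 0 || c <= 0) stopf("age_risk_constants: require b >= 0 and c > 0")
  structure(list(b = b, c = c, d = d), class = "age_risk_constants")
}

#' Age-dependent risk weight
#'
#' @param n age category, integer in `1..14`.
#' @param consts an [age_risk_constants()].
#' @return `b * exp(c * n) + d` (vectorized over `n`).
#' @export
age_risk_weight <- function(n, consts = age_risk_constants()) {
  if (any(n < 1 | n > 14 | n != round(n))) {
    stopf("age_risk_weight: n must be integers in 1..14")
  }
  consts$b * exp(consts$c * n) + consts$d
}

#' Age-weighted population risk sum
#'
#' @param pop an `age_composition`: 14 nonnegative fractions over the adult
#'   age categories, summing to 1.
#' @param consts an [age_risk_constants()].
#' @return `sum_n P(n) * (b e^(c n) + d)`.
#' @export
population_risk_sum <- function(pop, consts = age_risk_constants()) {
  pop <- as.numeric(pop)
  if (length(pop) != 14L || any(pop < 0)) {
    stopf("population_risk_sum: pop must be 14 nonnegative fractions")
  }
  if (abs(sum(pop) - 1) > 1e-6) {
    stopf("population_risk_sum: fractions sum to %.8f, not 1", sum(pop))
  }
  sum(pop * age_risk_weight(1:14, consts))
}

#' Adaptation coefficient k
#'
#' `k = f * adaptation_avg + g`; when `f` is absent (`NULL`/`NA`, the
#' outdoor thermophysiological case) `k = g` regardless of the average.
#'
#' @param f adaptation slope, or `NULL`/`NA` when absent.
#' @param g adaptation intercept.
#' @param adaptation_avg weighted average of the input over the previous J
#'   days (vectorized).
#' @return k (vectorized).
#' @export
adaptation_coefficient <- function(f, g, adaptation_avg) {
  if (f_absent(f)) rep(g, length.out = max(1L, length(adaptation_avg)))
  else f * adaptation_avg + g
}

#' Per-location-class model parameters
#'
#' One parameter block of the morbidity model. For thermophysiological
#' inputs (`sweating`, `core_temperature_increase`) the offset `l` must be
#' -1 so that estimates converge to zero at zero heat load.
#'
#' @param a positive scale.
#' @param l offset (exactly -1 for thermophysiological inputs).
#' @param f adaptation slope; `NA`/`NULL` when absent.
#' @param g adaptation intercept.
#' @param input_kind `"average_temperature"`, `"sweating"` or
#'   `"core_temperature_increase"`.
#' @param J adaptation window length, days.
#' @param weight_shape weight shape of the adaptation window.
#' @return An object of class `risk_class_params`.
#' @export
risk_class_params <- function(a, l, f, g,
                              input_kind = c("average_temperature", "sweating",
                                             "core_temperature_increase"),
                              J = 40, weight_shape = "linear_decreasing") {
  input_kind <- match.arg(input_kind)
  if (!is.numeric(a) || a <= 0) stopf("risk_class_params: a must be positive")
  if (input_kind != "average_temperature" && abs(l - (-1)) > 1e-12) {
    stopf("risk_class_params: l must be exactly -1 for input kind '%s'", input_kind)
  }
  structure(list(a = a, l = l, f = if (f_absent(f)) NA_real_ else f, g = g,
                 input_kind = input_kind,
                 adaptation = adaptation_config(J, weight_shape)),
            class = "risk_class_params")
}

#' Full model parameter set
#'
#' @param indoor,outdoor [risk_class_params()] for each location class.
#' @param consts an [age_risk_constants()].
#' @return An object of class `risk_parameters`.
#' @export
risk_parameters <- function(indoor, outdoor, consts = age_risk_constants()) {
  stopifnot(inherits(indoor, "risk_class_params"),
            inherits(outdoor, "risk_class_params"))
  structure(list(indoor = indoor, outdoor = outdoor, consts = consts),
            class = "risk_parameters")
}

#' Expected indoor daily count
#'
#' @param params a `risk_class_params` for the indoor class (supplies `a`, `l`).
#' @param k adaptation coefficient for the day (vectorized).
#' @param lag_input three-day weighted input `0.6 x0 + 0.2 x1 + 0.2 x2`.
#' @param pop_sum [population_risk_sum()] value.
#' @return Expected count, floored at 0.
#' @export
estimate_indoor <- function(params, k, lag_input, pop_sum) {
  e <- exp(k * lag_input)
  if (any(!is.finite(e[!is.na(e)]))) stopf("estimate_indoor: non-finite exponent")
  pmax(0, params$a * (e + params$l) * pop_sum)
}

#' Expected outdoor daily count
#'
#' @param params a `risk_class_params` for the outdoor class.
#' @param k adaptation coefficient for the day (vectorized).
#' @param x0 same-day input value.
#' @param pop_sum [population_risk_sum()] value.
#' @return Expected count, floored at 0.
#' @export
estimate_outdoor <- function(params, k, x0, pop_sum) {
  e <- exp(k * x0)
  if (any(!is.finite(e[!is.na(e)]))) stopf("estimate_outdoor: non-finite exponent")
  pmax(0, params$a * (e + params$l) * pop_sum)
}

# Per-day model inputs (u = lagged input entering the exponent, A =
# adaptation average) for one location class, season by season so that lag
# windows never cross season boundaries. Returns vectors aligned to
# `exposure` rows with NA where history is insufficient.
class_model_inputs <- function(exposure, class_params, location) {
  x <- exposure_input(exposure, class_params$input_kind)
  u <- rep(NA_real_, nrow(exposure))
  A <- rep(NA_real_, nrow(exposure))
  J <- class_params$adaptation$J
  for (s in unique(exposure$season)) {
    sel <- which(exposure$season == s)
    xs <- x[sel]
    if (location == "indoor") {
      if (length(xs) >= 3L) u[sel] <- indoor_lag_input(xs)
    } else {
      u[sel] <- xs
    }
    if (!f_absent(class_params$f)) {
      if (length(xs) > J) A[sel] <- adaptation_average(xs, class_params$adaptation)
    } else {
      A[sel] <- 0  # k = g; average unused
    }
  }
  list(u = u, A = A)
}

#' Daily estimates over an exposure series
#'
#' Evaluates the full model per day. Days lacking the lag or adaptation
#' history required by either location class are excluded (seasons are
#' processed independently; windows never cross season boundaries).
#'
#' @param exposure an `exposure_series`.
#' @param pop an `age_composition` (14 fractions).
#' @param params a [risk_parameters()].
#' @return Data frame of class `daily_estimate` with columns `date`,
#'   `season`, `y_in`, `y_out`, `y`.
#' @export
estimate_series <- function(exposure, pop, params) {
  S <- population_risk_sum(pop, params$consts)
  min_hist <- max(params$indoor$adaptation$J * !f_absent(params$indoor$f),
                  params$outdoor$adaptation$J * !f_absent(params$outdoor$f),
                  2L)
  mi_in <- class_model_inputs(exposure, params$indoor, "indoor")
  mi_out <- class_model_inputs(exposure, params$outdoor, "outdoor")
  k_in <- adaptation_coefficient(params$indoor$f, params$indoor$g, mi_in$A)
  k_out <- adaptation_coefficient(params$outdoor$f, params$outdoor$g, mi_out$A)
  y_in <- estimate_indoor(params$indoor, k_in, mi_in$u, S)
  y_out <- estimate_outdoor(params$outdoor, k_out, mi_out$u, S)
  keep <- !is.na(y_in) & !is.na(y_out)
  # enforce a common history cut so output length is predictable per season
  for (s in unique(exposure$season)) {
    sel <- which(exposure$season == s)
    if (length(sel) > min_hist) keep[sel[seq_len(min_hist)]] <- FALSE
    else keep[sel] <- FALSE
  }
  if (!any(keep)) stopf("estimate_series: no day has the required history")
  out <- data.frame(date = exposure$date[keep], season = exposure$season[keep],
                    y_in = y_in[keep], y_out = y_out[keep],
                    y = y_in[keep] + y_out[keep])
  structure(out, class = c("daily_estimate", "data.frame"))
}

#' Bootstrap 95 % band from per-fold parameter sets
#'
#' Residual-free parameter bootstrap over the held-out-year parameter sets
#' of a cross-validated fit: parameter sets are resampled with replacement,
#' averaged, and the model re-evaluated; the band is the per-day quantile
#' envelope. The construction of the published band is not specified; this
#' is the package's documented choice.
#'
#' @param param_sets list of [risk_parameters()] (one per held-out year).
#' @param exposure an `exposure_series`.
#' @param pop an `age_composition`.
#' @param level coverage (default 0.95).
#' @param n_boot bootstrap resamples (default 200).
#' @param seed RNG seed.
#' @return `daily_estimate` for the averaged parameters with extra columns
#'   `lo`, `hi`.
#' @export
estimate_band <- function(param_sets, exposure, pop, level = 0.95,
                          n_boot = 200, seed = 1) {
  stopifnot(length(param_sets) >= 2L)
  center <- estimate_series(exposure, pop, average_parameters(param_sets))
  preds <- with_seed(seed, {
    lapply(seq_len(n_boot), function(b) {
      pick <- sample(length(param_sets), replace = TRUE)
      estimate_series(exposure, pop, average_parameters(param_sets[pick]))$y
    })
  })
  mat <- do.call(cbind, preds)
  alpha <- (1 - level) / 2
  # quantile envelope, widened (if ever needed) to bracket the point estimate
  center$lo <- pmin(apply(mat, 1, quantile, probs = alpha), center$y)
  center$hi <- pmax(apply(mat, 1, quantile, probs = 1 - alpha), center$y)
  center
}

#' Arithmetic mean of parameter sets
#'
#' Element-wise mean of `a`, `l`, `f`, `g` across [risk_parameters()] sets
#' (the across-fold "averaged over the multi-year time frame" parameters).
#' Structural fields (input kind, window) must agree.
#'
#' @param param_sets list of [risk_parameters()].
#' @return A single [risk_parameters()].
#' @export
average_parameters <- function(param_sets) {
  avg_class <- function(cls_list) {
    ref <- cls_list[[1]]
    mn <- function(field) mean(vapply(cls_list, function(p) p[[field]], numeric(1)))
    f <- if (f_absent(ref$f)) NA_real_ else mn("f")
    risk_class_params(a = mn("a"), l = mn("l"), f = f, g = mn("g"),
                      input_kind = ref$input_kind, J = ref$adaptation$J,
                      weight_shape = ref$adaptation$weight_shape)
  }
  risk_parameters(
    indoor = avg_class(lapply(param_sets, `[[`, "indoor")),
    outdoor = avg_class(lapply(param_sets, `[[`, "outdoor")),
    consts = param_sets[[1]]$consts
  )
}
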