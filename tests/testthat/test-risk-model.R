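test_that("age risk weight follows b e^(cn) + d", {
  # direct arithmetic with the cited constants: 0.171 e^0.494 + 190.7
  expect_equal(age_risk_weight(1), 0.171 * exp(0.494) + 190.7)
  expect_equal(age_risk_weight(1), 190.98025, tolerance = 1e-6)
  w <- age_risk_weight(1:14)
  expect_true(all(diff(w) > 0))
  expect_equal(age_risk_weight(5, age_risk_constants(b = 0)), 190.7)
  expect_error(age_risk_weight(0), "1..14")
  expect_error(age_risk_weight(15), "1..14")
})

test_that("population risk sum is the P-weighted mean of the age weights", {
  point <- structure(c(1, rep(0, 13)), class = "age_composition")
  expect_equal(population_risk_sum(point), age_risk_weight(1))
  unif <- generate_age_composition(0)
  expect_equal(population_risk_sum(unif), mean(age_risk_weight(1:14)))
  old <- structure(c(rep(0, 13), 1), class = "age_composition")
  expect_gt(population_risk_sum(old), population_risk_sum(point))
  bad <- structure(rep(0.1, 14), class = "age_composition")
  expect_error(population_risk_sum(bad), "sum")
})

test_that("adaptation coefficient handles slope, zero and absent f", {
  expect_equal(adaptation_coefficient(0, 0.5, 99), 0.5)
  expect_equal(adaptation_coefficient(-0.00697, 0.631, 25), 0.45675)
  expect_equal(adaptation_coefficient(NA, 0.7, 123), 0.7)
  expect_equal(adaptation_coefficient(NULL, 0.7, c(1, 2)), c(0.7, 0.7))
})

test_that("indoor and outdoor single-day estimates match direct arithmetic", {
  pin <- risk_class_params(a = 1e-3, l = -1, f = NA, g = 1,
                           input_kind = "sweating", J = 5)
  expect_equal(estimate_indoor(pin, k = 0.5, lag_input = 26, pop_sum = 300),
               1e-3 * (exp(0.5 * 26) - 1) * 300)
  expect_equal(estimate_indoor(pin, k = 0.5, lag_input = 0, pop_sum = 300), 0)
  pin2 <- pin; pin2$a <- 2e-3
  expect_equal(estimate_indoor(pin2, 0.5, 26, 300),
               2 * estimate_indoor(pin, 0.5, 26, 300))

  pout <- risk_class_params(a = 0.4, l = -1, f = NA, g = 1,
                            input_kind = "sweating", J = 5)
  expect_equal(estimate_outdoor(pout, k = 0.3, x0 = 7, pop_sum = 200),
               0.4 * (exp(2.1) - 1) * 200)
  expect_equal(estimate_outdoor(pout, k = 0, x0 = 123, pop_sum = 200), 0)
  expect_equal(estimate_outdoor(pout, k = 0.3, x0 = 0, pop_sum = 200), 0)
  # floor: very negative offset pins cool days at zero
  ptemp <- risk_class_params(a = 1e-6, l = -1e5, f = NA, g = 0.4,
                             input_kind = "average_temperature", J = 5)
  expect_equal(estimate_indoor(ptemp, 0.4, 10, 250), 0)
})

test_that("estimate_series composes the pieces and drops short-history days", {
  dates <- seq(as.Date("2019-06-01"), by = 1, length.out = 30)
  set.seed(21)
  x <- runif(30, 0, 2)
  ex <- make_exposure(dates, mean_temp = 25, core = x)
  params <- risk_parameters(
    risk_class_params(a = 0.02, l = -1, f = -1.5, g = 4, J = 10,
                      input_kind = "core_temperature_increase"),
    risk_class_params(a = 0.03, l = -1, f = NA, g = 3, J = 10,
                      input_kind = "core_temperature_increase")
  )
  est <- estimate_series(ex, fix_pop(), params)
  expect_equal(nrow(est), 30 - 10)  # length = n - max(J_in, J_out, 2)

  S <- population_risk_sum(fix_pop())
  t <- 15
  u_in <- 0.6 * x[t] + 0.2 * x[t - 1] + 0.2 * x[t - 2]
  A <- sum(adaptation_weights(adaptation_config(10)) * x[(t - 1):(t - 10)])
  k_in <- -1.5 * A + 4
  by_hand <- estimate_indoor(params$indoor, k_in, u_in, S) +
    estimate_outdoor(params$outdoor, 3, x[t], S)
  expect_equal(est$y[est$date == dates[t]], by_hand)
  expect_equal(est$y, est$y_in + est$y_out)
})

test_that("estimates are nonnegative and homogeneous in the scales", {
  ex <- fix_exposure_temp()
  set.seed(5)
  for (rep in 1:5) {
    params <- risk_parameters(
      risk_class_params(a = 10^runif(1, -8, -6), l = runif(1, -3e4, 0),
                        f = runif(1, -0.01, 0), g = runif(1, 0.3, 0.7),
                        input_kind = "average_temperature", J = sample(5:40, 1)),
      risk_class_params(a = 10^runif(1, -7, -5), l = runif(1, -5e3, 0),
                        f = runif(1, -0.01, 0), g = runif(1, 0.3, 0.6),
                        input_kind = "average_temperature", J = sample(5:40, 1))
    )
    est <- estimate_series(ex, fix_pop(), params)
    expect_true(all(est$y_in >= 0) && all(est$y_out >= 0) && all(est$y >= 0))
    s <- 3.7
    p2 <- params
    p2$indoor$a <- p2$indoor$a * s
    p2$outdoor$a <- p2$outdoor$a * s
    est2 <- estimate_series(ex, fix_pop(), p2)
    expect_equal(est2$y, s * est$y, tolerance = 1e-12)
  }
})

test_that("k decreases as the trailing average warms when f < 0", {
  x <- seq(20, 32, length.out = 60)  # monotone warming season
  A <- adaptation_average(x, adaptation_config(10))
  k <- adaptation_coefficient(-0.007, 0.63, A[11:60])
  expect_true(all(diff(k) < 0))
})

test_that("parameter averaging is the arithmetic mean per field", {
  mk <- function(a, g) risk_parameters(
    risk_class_params(a = a, l = -1, f = -2, g = g, J = 10,
                      input_kind = "core_temperature_increase"),
    risk_class_params(a = a / 2, l = -1, f = NA, g = g / 2, J = 10,
                      input_kind = "core_temperature_increase")
  )
  avg <- average_parameters(list(mk(0.1, 4), mk(0.3, 6)))
  expect_equal(avg$indoor$a, 0.2)
  expect_equal(avg$indoor$g, 5)
  expect_equal(avg$outdoor$a, 0.1)
  expect_true(is.na(avg$outdoor$f))
})

test_that("bootstrap band brackets the averaged-parameter estimate", {
  dates <- seq(as.Date("2019-06-01"), by = 1, length.out = 40)
  set.seed(2)
  ex <- make_exposure(dates, mean_temp = 25, core = runif(40, 0, 1.5))
  mk <- function(a) risk_parameters(
    risk_class_params(a = a, l = -1, f = -1, g = 3.5, J = 8,
                      input_kind = "core_temperature_increase"),
    risk_class_params(a = a, l = -1, f = NA, g = 3, J = 8,
                      input_kind = "core_temperature_increase")
  )
  sets <- lapply(c(0.02, 0.025, 0.03, 0.022, 0.028), mk)
  band <- estimate_band(sets, ex, fix_pop(), n_boot = 100, seed = 4)
  expect_true(all(band$lo <= band$y + 1e-9))
  expect_true(all(band$hi >= band$y - 1e-9))
  expect_true(all(band$lo <= band$hi))
})

test_that("parameter constructors enforce the l = -1 rule and positivity", {
  expect_error(risk_class_params(a = -1, l = -1, f = NA, g = 1,
                                 input_kind = "sweating"), "positive")
  expect_error(risk_class_params(a = 1, l = -0.5, f = NA, g = 1,
                                 input_kind = "sweating"), "-1")
  expect_silent(risk_class_params(a = 1, l = -5e3, f = -0.01, g = 0.5,
                                  input_kind = "average_temperature"))
})
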