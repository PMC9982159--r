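# Noiseless self-consistency oracles for every fitting stage, plus the
# bookkeeping and robustness contracts. Stochastic (Poisson) recovery rates
# are asserted in test-acceptance.R.

noiseless_temp_data <- function() {
  ex <- fix_exposure_temp()
  spec <- true_model_spec(default_parameters("average_temperature"), noise = "none")
  list(ex = ex, spec = spec,
       counts = generate_patient_counts(ex, fix_pop(), spec))
}

test_that("fit_scale_offset recovers (a, l) given the true k", {
  d <- noiseless_temp_data()
  tr <- d$spec$params$indoor
  cfg <- fit_config("average_temperature", "indoor", J = 40)
  # true per-day k over the usable fitting days
  dat <- heatmorb:::prepare_fit_data(d$counts, d$ex, fix_pop(), cfg)
  k <- tr$f * dat$A + tr$g
  got <- fit_scale_offset(d$counts, d$ex, fix_pop(), k, cfg)
  expect_lt(abs(got$a - tr$a) / tr$a, 1e-6)
  expect_lt(abs(got$l - tr$l) / abs(tr$l), 1e-6)

  # doubling all counts doubles a, l pinned under the fixed policy
  spec_sw <- true_model_spec(default_parameters("sweating"), noise = "none")
  dates <- seq(as.Date("2019-06-01"), by = 1, length.out = 90)
  set.seed(9)
  exsw <- make_exposure(dates, mean_temp = 25, sweat = runif(90, 0, 2000))
  cnt1 <- generate_patient_counts(exsw, fix_pop(), spec_sw)
  cfg_o <- fit_config("sweating", "outdoor", J = 30)
  k_o <- spec_sw$params$outdoor$g
  f1 <- fit_scale_offset(cnt1, exsw, fix_pop(), k_o, cfg_o)
  cnt2 <- cnt1
  cnt2$indoor <- cnt2$indoor * 2; cnt2$outdoor <- cnt2$outdoor * 2
  cnt2$total <- cnt2$total * 2
  f2 <- fit_scale_offset(cnt2, exsw, fix_pop(), k_o, cfg_o)
  expect_equal(f2$a, 2 * f1$a, tolerance = 1e-12)
  expect_equal(f2$l, -1)

  # all-zero counts with zero exposure: a unidentifiable, flagged 0
  ex0 <- make_exposure(dates, mean_temp = 25, sweat = 0)
  cnt0 <- generate_patient_counts(ex0, fix_pop(), spec_sw)
  f0 <- fit_scale_offset(cnt0, ex0, fix_pop(), 1e-3, cfg_o)
  expect_equal(f0$a, 0)
  expect_equal(f0$flag, "unidentifiable")

  # constant exposure with a free offset: a and l are not separable
  exc <- make_exposure(dates, mean_temp = 25)
  spec_t <- true_model_spec(default_parameters("average_temperature"), noise = "none")
  cntc <- generate_patient_counts(exc, fix_pop(), spec_t)
  cfg_t <- fit_config("average_temperature", "indoor", J = 10)
  expect_error(fit_scale_offset(cntc, exc, fix_pop(), 0.45, cfg_t), "degenerate")
})

test_that("fit_adaptation recovers (f, g) given the true (a, l)", {
  d <- noiseless_temp_data()
  tr <- d$spec$params$indoor
  cfg <- fit_config("average_temperature", "indoor", J = 40)
  got <- fit_adaptation(d$counts, d$ex, fix_pop(), tr$a, tr$l, cfg)
  expect_lt(abs(got$f - tr$f) / abs(tr$f), 1e-4)
  expect_lt(abs(got$g - tr$g) / tr$g, 1e-4)

  # f_policy absent: one-parameter reduced model
  spec_sw <- true_model_spec(default_parameters("sweating"), noise = "none")
  ex_th <- fix_exposure_thermo()
  cnt_sw <- generate_patient_counts(ex_th, fix_pop(), spec_sw)
  cfg_o <- fit_config("sweating", "outdoor", J = 30)
  tro <- spec_sw$params$outdoor
  got_o <- fit_adaptation(cnt_sw, ex_th, fix_pop(), tro$a, -1, cfg_o)
  expect_true(is.na(got_o$f))
  expect_lt(abs(got_o$g - tro$g) / tro$g, 1e-4)

  # data generated with f* = 0: fitted slope is (numerically) null
  p0 <- default_parameters("average_temperature")
  p0$indoor$f <- 0
  p0$outdoor$f <- 0
  spec0 <- true_model_spec(p0, noise = "none")
  cnt0 <- generate_patient_counts(d$ex, fix_pop(), spec0)
  got0 <- fit_adaptation(cnt0, d$ex, fix_pop(), p0$indoor$a, p0$indoor$l, cfg)
  expect_lt(abs(got0$f), 1e-6)
})

test_that("fit_iterative converges to the generating parameters in few iterations", {
  d <- noiseless_temp_data()
  for (loc in c("indoor", "outdoor")) {
    tr <- d$spec$params[[loc]]
    cfg <- fit_config("average_temperature", loc, J = tr$adaptation$J)
    fit <- fit_iterative(d$counts, d$ex, fix_pop(), cfg)
    expect_true(fit$converged)
    expect_lte(fit$iterations, 10)
    p <- fit$parameters
    expect_lt(abs(p$a - tr$a) / tr$a, 1e-4)
    expect_lt(abs(p$l - tr$l) / abs(tr$l), 1e-4)
    expect_lt(abs(p$f - tr$f) / abs(tr$f), 1e-4)
    expect_lt(abs(p$g - tr$g) / tr$g, 1e-4)
  }
})

test_that("refitting its own noiseless output is a fixed point", {
  d <- noiseless_temp_data()
  cfg <- fit_config("average_temperature", "indoor", J = 40)
  fit1 <- fit_iterative(d$counts, d$ex, fix_pop(), cfg)
  params1 <- heatmorb:::fitted_class_params(fit1)
  spec1 <- true_model_spec(risk_parameters(params1, d$spec$params$outdoor),
                           noise = "none")
  cnt1 <- generate_patient_counts(d$ex, fix_pop(), spec1)
  fit2 <- fit_iterative(cnt1, d$ex, fix_pop(), cfg)
  expect_lt(abs(fit2$parameters$a - params1$a) / params1$a, 1e-6)
  expect_lt(abs(fit2$parameters$g - params1$g) / params1$g, 1e-6)
})

test_that("objective trace is non-increasing for both objectives", {
  ex <- fix_exposure_thermo()
  spec <- true_model_spec(default_parameters("sweating"), noise = "poisson")
  cnt <- generate_patient_counts(ex, fix_pop(), spec, seed = 77)
  for (ob in c("ols", "poisson")) {
    cfg <- fit_config("sweating", "indoor", J = 40, objective = ob)
    fit <- fit_iterative(cnt, ex, fix_pop(), cfg)
    tr <- fit$objective_trace
    expect_gte(length(tr), 2)
    expect_true(all(diff(tr) <= 1e-8 * (abs(tr[-length(tr)]) + 1)))
  }
})

test_that("loocv by year: bookkeeping, exchangeability and perfect-model R2", {
  # identical noiseless years: noise-free weather repeats exactly
  sc <- weather_scenario(n_years = 4, noise_sd = 0, rh_noise_sd = 0, seed = 2)
  ex <- build_exposure(generate_weather(sc))
  spec <- true_model_spec(default_parameters("average_temperature"), noise = "none")
  cnt <- generate_patient_counts(ex, fix_pop(), spec)
  cfg_i <- fit_config("average_temperature", "indoor", J = 40)
  cfg_o <- fit_config("average_temperature", "outdoor", J = 30)
  cv <- loocv_by_year(cnt, ex, fix_pop(), cfg_i, cfg_o)
  expect_length(cv$per_year, 4)
  expect_equal(sort(unique(cv$predictions$year)), 2013:2016)
  a_by_fold <- vapply(cv$per_year, function(p) p$params$indoor$a, numeric(1))
  expect_lt(diff(range(a_by_fold)) / mean(a_by_fold), 1e-8)
  expect_true(all(abs(cv$r2_by_year$r2_total - 1) < 1e-9))
  expect_true(all(abs(cv$r2_by_year$r2_indoor - 1) < 1e-9))
  # averaged parameters reproduce any single fold on identical years
  expect_equal(cv$averaged$indoor$a, a_by_fold[[1]], tolerance = 1e-9)
  expect_error(loocv_by_year(cnt[cnt$season < 2015, ], ex, fix_pop(),
                             cfg_i, cfg_o), "3 years")
})

test_that("window scan bookkeeping: one row per feasible J, oversized J skipped", {
  sc <- weather_scenario(n_years = 3, seed = 6)
  ex <- build_exposure(generate_weather(sc))
  spec <- true_model_spec(default_parameters("average_temperature"), noise = "poisson")
  cnt <- generate_patient_counts(ex, fix_pop(), spec, seed = 3)
  cfg_i <- fit_config("average_temperature", "indoor")
  cfg_o <- fit_config("average_temperature", "outdoor")
  expect_warning(
    tab <- scan_adaptation_window(cnt, ex, fix_pop(), cfg_i, cfg_o,
                                  J_values = c(10, 30, 200)),
    "exceeds"
  )
  expect_equal(tab$J, c(10, 30))
  expect_true(all(tab$r2_indoor <= 1 & tab$r2_outdoor <= 1))
})

test_that("poisson objective is rejected with a free l", {
  expect_error(fit_config("average_temperature", "indoor", objective = "poisson"),
               "fixed-l")
})
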