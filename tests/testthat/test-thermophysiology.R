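test_that("subject model validates its physiology", {
  expect_s3_class(subject_model(), "subject_model")
  expect_error(subject_model(metabolic_rate = -10), "positive")
  expect_error(subject_model(core_setpoint = 33, skin_setpoint = 34), "setpoint")
  expect_error(subject_model(body_mass = NA), "finite")
})

test_that("controllers are off below the setpoints", {
  s <- subject_model()
  fl <- heatmorb:::two_node_fluxes(s$core_setpoint - 0.2, s$skin_setpoint - 0.2,
                                   25, 50, s)
  expect_equal(fl$sweat_rate, 0)
  # constriction (cold skin signal) can only reduce flow below basal
  expect_lte(fl$skin_blood_flow, s$basal_skin_blood_flow)
  fl2 <- heatmorb:::two_node_fluxes(s$core_setpoint - 0.2, s$skin_setpoint,
                                    25, 50, s)
  expect_equal(fl2$skin_blood_flow, s$basal_skin_blood_flow)
})

test_that("a settled state stays put and hotter ambient heats the core faster", {
  s <- subject_model()
  # drive to steady state at 28 degC / 50 %
  st <- thermo_state(s$core_setpoint, s$skin_setpoint)
  for (i in 1:3000) st <- step_heat_balance(st, 28, 50, s, dt = 60)
  st2 <- step_heat_balance(st, 28, 50, s, dt = 60)
  expect_lt(abs(st2$core_temp - st$core_temp), 1e-6)
  expect_lt(abs(st2$skin_temp - st$skin_temp), 1e-6)

  # fixed state, two ambients: core heating rate nondecreasing in T
  st0 <- thermo_state(37.0, 34.5)
  warm1 <- step_heat_balance(st0, 32, 50, s, 60)$core_temp
  warm2 <- step_heat_balance(st0, 38, 50, s, 60)$core_temp
  expect_gte(warm2, warm1)

  expect_error(step_heat_balance(st0, 30, 120, s, 60), "rh")
  expect_error(step_heat_balance(st0, 30, 50, s, 400), "dt")
  bad <- thermo_state(46, 40)
  expect_error(step_heat_balance(bad, 30, 50, s, 60), "instability")
})

test_that("single steps and the season integrator share the same dynamics", {
  s <- subject_model()
  w <- const_weather(36, 55, days = 1)
  d <- simulate_season(w, s, dt = 60, keep_trajectory = TRUE)
  traj <- attr(d, "trajectory")
  st <- thermo_state(s$core_setpoint, s$skin_setpoint)
  for (i in 1:50) st <- step_heat_balance(st, 36, 55, s, dt = 60)
  expect_equal(traj$core_temp[51], st$core_temp, tolerance = 1e-12)
  expect_equal(traj$skin_temp[51], st$skin_temp, tolerance = 1e-12)
  expect_equal(traj$cumulative_sweat[50], st$cumulative_sweat, tolerance = 1e-9)
})

test_that("hot constant day matches its fine-step reference and dt refinement converges", {
  s <- subject_model()
  w <- const_weather(40, 60, days = 1)
  d60 <- simulate_season(w, s, dt = 60)
  expect_gt(d60$peak_core_increase_c, 0)
  expect_gt(d60$total_sweat_g, 0)
  d30 <- simulate_season(w, s, dt = 30)
  expect_lt(abs(d60$peak_core_increase_c - d30$peak_core_increase_c), 0.01)
  # dt = 1 s oracle for the frozen reference values
  d1 <- simulate_season(w, s, dt = 1)
  expect_lt(abs(d60$peak_core_increase_c - d1$peak_core_increase_c), 0.01)
  expect_lt(abs(d60$total_sweat_g - d1$total_sweat_g) / d1$total_sweat_g, 0.02)
})

test_that("weather gaps and cumulative sweat behave", {
  s <- subject_model()
  w <- const_weather(30, 60, days = 1)
  wg <- w[-(5:10), ]  # 6 h hole
  expect_error(simulate_season(wg, s), "gap")
  d <- simulate_season(w, s, keep_trajectory = TRUE)
  traj <- attr(d, "trajectory")
  expect_true(all(diff(traj$cumulative_sweat) >= 0))
})

test_that("heat-balance residual vanishes at steady state and tracks storage in transients", {
  s <- subject_model()
  w <- const_weather(34, 50, days = 4)
  d <- simulate_season(w, s, keep_trajectory = TRUE)
  traj <- attr(d, "trajectory")
  expect_lt(heat_balance_residual(traj, s), 0.01 * s$metabolic_rate)

  # transient: residual equals the whole-body storage rate, recomputed
  # independently from the trajectory's finite differences
  i <- 30  # early transient
  resid <- heat_balance_residual(traj, s, at = i)
  dt <- as.numeric(diff(traj$time[1:2]), units = "secs")
  storage <- (s$core_heat_capacity * (traj$core_temp[i + 1] - traj$core_temp[i]) +
              s$skin_heat_capacity * (traj$skin_temp[i + 1] - traj$skin_temp[i])) / dt
  expect_equal(resid, abs(storage), tolerance = 1e-8)

  # degenerate: (near) zero metabolism, ambient at skin temp, saturated air
  s0 <- subject_model(metabolic_rate = 1e-9)
  fl <- heatmorb:::two_node_fluxes(s0$skin_setpoint, s0$skin_setpoint,
                                   s0$skin_setpoint, 100, s0)
  expect_lt(abs(fl$q_dry), 1e-9)
  expect_equal(fl$sweat_rate, 0)
  expect_lt(fl$e_sk, 0.5)  # only passive diffusion against near-zero gradient
})

test_that("daily outputs are monotone in ambient temperature and humidity", {
  s <- subject_model()
  base <- simulate_season(const_weather(35, 50, days = 2), s)
  hotter <- simulate_season(const_weather(37, 50, days = 2), s)
  expect_true(all(hotter$peak_core_increase_c >= base$peak_core_increase_c))
  expect_true(all(hotter$total_sweat_g >= base$total_sweat_g))
  # above sweating onset, more humid -> harder evaporation -> more strain
  humid <- simulate_season(const_weather(35, 80, days = 2), s)
  expect_true(all(humid$peak_core_increase_c >= base$peak_core_increase_c))
})
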