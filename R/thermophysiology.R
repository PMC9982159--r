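# Two-node (core/skin) thermoregulation surrogate.
#
# Fixed physical constants of the lumped model. Control gains and subject
# geometry live in `subject_model()`; these are physics, not tunables.
.thermo_const <- list(
  k_min        = 5.28,    # minimum core->skin tissue conductance, W/(m^2 K)
  blood_heat   = 1.163,   # heat equivalent of skin blood flow, W/(m^2 K) per L/(m^2 h)
  h_conv       = 3.1,     # still-air convective coefficient, W/(m^2 K)
  h_rad        = 4.7,     # linearized radiative coefficient, W/(m^2 K)
  lewis        = 16.5,    # Lewis relation, K/kPa
  lambda_sweat = 2426,    # latent heat of evaporated sweat, J/g
  shiver_gain  = 19.4,    # shivering metabolism gain, W/m^2 per K^2
  skbf_min     = 0.5,     # vasoconstriction floor on skin blood flow, L/(m^2 h)
  core_bounds  = c(30, 45),  # validity envelope for the core node, degC
  skin_bounds  = c(15, 45)   # instability envelope for the skin node, degC
)

#' Standard-subject parameterization of the two-node model
#'
#' Lumped-parameter description of a resting, lightly clothed adult used by
#' [simulate_season()]. Defaults describe a 70 kg subject at 1 met whose
#' steady state at 28 degC / 50 % relative humidity is thermoneutral (no
#' active sweating, core at its setpoint).
#'
#' @param body_mass body mass, kg.
#' @param body_surface_area DuBois surface area, m^2.
#' @param metabolic_rate whole-body resting metabolic rate, W.
#' @param core_heat_capacity,skin_heat_capacity lumped heat capacities of the
#'   core and skin nodes, J/K.
#' @param basal_skin_blood_flow basal skin blood flow, L/(m^2 h).
#' @param vasodilation_gain skin blood flow increase per K of core warm
#'   signal, L/(m^2 h K).
#' @param vasoconstriction_gain divisor gain on skin blood flow per K of skin
#'   cold signal, 1/K.
#' @param max_skin_blood_flow upper bound on skin blood flow, L/(m^2 h).
#' @param sweating_gain regulatory sweat rate per K of weighted warm signal,
#'   g/(m^2 h K).
#' @param max_sweat_rate whole-body cap on regulatory sweating, g/h.
#' @param core_setpoint,skin_setpoint thermoregulatory setpoints, degC.
#'   `core_setpoint` must exceed `skin_setpoint`.
#' @param clothing_insulation clothing insulation, clo (1 clo = 0.155 m^2 K/W).
#'
#' @return An object of class `subject_model`.
#' @export
subject_model <- function(body_mass = 70,
                          body_surface_area = 1.87,
                          metabolic_rate = 105,
                          core_heat_capacity = 0.9 * 70 * 3500,
                          skin_heat_capacity = 0.1 * 70 * 3500,
                          basal_skin_blood_flow = 11,
                          vasodilation_gain = 75,
                          vasoconstriction_gain = 0.5,
                          max_skin_blood_flow = 90,
                          sweating_gain = 170,
                          max_sweat_rate = 900,
                          core_setpoint = 36.8,
                          skin_setpoint = 34.0,
                          clothing_insulation = 0.1) {
  s <- list(
    body_mass = body_mass, body_surface_area = body_surface_area,
    metabolic_rate = metabolic_rate,
    core_heat_capacity = core_heat_capacity,
    skin_heat_capacity = skin_heat_capacity,
    basal_skin_blood_flow = basal_skin_blood_flow,
    vasodilation_gain = vasodilation_gain,
    vasoconstriction_gain = vasoconstriction_gain,
    max_skin_blood_flow = max_skin_blood_flow,
    sweating_gain = sweating_gain, max_sweat_rate = max_sweat_rate,
    core_setpoint = core_setpoint, skin_setpoint = skin_setpoint,
    clothing_insulation = clothing_insulation
  )
  num <- vapply(s, function(x) is.numeric(x) && length(x) == 1L && is.finite(x), logical(1))
  if (!all(num)) stopf("subject_model: all fields must be finite scalars")
  pos <- setdiff(names(s), "clothing_insulation")
  if (any(vapply(s[pos], function(x) x <= 0, logical(1)))) {
    stopf("subject_model: all physiological fields must be positive")
  }
  if (clothing_insulation < 0) stopf("subject_model: clothing_insulation must be >= 0")
  if (core_setpoint <= skin_setpoint) {
    stopf("subject_model: core_setpoint must exceed skin_setpoint")
  }
  structure(s, class = "subject_model")
}

#' Instantaneous thermophysiological state
#'
#' @param core_temp,skin_temp node temperatures, degC.
#' @param cumulative_sweat regulatory sweat secreted so far, g.
#' @param time timestamp (POSIXct) or `NA`.
#' @return An object of class `thermo_state`.
#' @export
thermo_state <- function(core_temp = 36.8, skin_temp = 34.0,
                         cumulative_sweat = 0, time = NA) {
  structure(list(core_temp = core_temp, skin_temp = skin_temp,
                 cumulative_sweat = cumulative_sweat, time = time),
            class = "thermo_state")
}

# Tetens saturated vapor pressure over water, kPa, T in degC.
saturated_vapor_pressure <- function(temp_c) {
  0.61078 * exp(17.27 * temp_c / (temp_c + 237.3))
}

# All instantaneous fluxes (W/m^2 unless noted) and controller outputs for a
# given state and environment. Single source of truth for both the stepper
# and the conservation check.
two_node_fluxes <- function(core_temp, skin_temp, ambient_temp, rh, subject) {
  cn <- .thermo_const
  area <- subject$body_surface_area
  m_area <- subject$metabolic_rate / area

  wsig_cr <- max(0, core_temp - subject$core_setpoint)
  wsig_sk <- max(0, skin_temp - subject$skin_setpoint)
  csig_cr <- max(0, subject$core_setpoint - core_temp)
  csig_sk <- max(0, subject$skin_setpoint - skin_temp)

  # Vasomotor control: dilation driven by the core, constriction by the skin.
  skbf <- (subject$basal_skin_blood_flow + subject$vasodilation_gain * wsig_cr) /
    (1 + subject$vasoconstriction_gain * csig_sk)
  skbf <- clip(skbf, cn$skbf_min, subject$max_skin_blood_flow)
  k_cs <- cn$k_min + cn$blood_heat * skbf

  # Shivering thermogenesis (product-of-cold-signals form).
  m_shiv <- cn$shiver_gain * csig_cr * csig_sk
  m_tot <- m_area + m_shiv

  pa <- rh / 100 * saturated_vapor_pressure(ambient_temp)
  p_sk <- saturated_vapor_pressure(skin_temp)

  # Respiratory losses (sensible + latent), standard empirical form.
  q_res <- 0.0014 * m_tot * (34 - ambient_temp) +
    0.0173 * m_tot * (5.87 - pa)

  # Dry and evaporative paths through clothing + boundary air layer.
  icl <- subject$clothing_insulation
  f_cl <- 1 + 0.31 * icl
  h <- cn$h_conv + cn$h_rad
  r_dry <- 0.155 * icl + 1 / (f_cl * h)          # m^2 K / W
  r_evap <- 0.0155 * icl + 1 / (f_cl * cn$lewis * cn$h_conv)  # m^2 kPa / W
  q_dry <- (skin_temp - ambient_temp) / r_dry

  e_max <- max(0, (p_sk - pa) / r_evap)

  # Regulatory sweating from a core-weighted warm signal, whole-body capped.
  sweat_signal <- 0.9 * wsig_cr + 0.1 * wsig_sk
  m_sw <- min(subject$sweating_gain * sweat_signal, subject$max_sweat_rate / area)
  e_rsw_req <- m_sw * cn$lambda_sweat / 3600
  e_rsw <- min(e_rsw_req, e_max)
  w_rsw <- if (e_max > 0) e_rsw / e_max else 0
  e_dif <- 0.06 * (1 - w_rsw) * e_max            # passive diffusion of the dry skin fraction
  e_sk <- e_rsw + e_dif

  core_flux <- m_tot - q_res - k_cs * (core_temp - skin_temp)   # W/m^2 into core
  skin_flux <- k_cs * (core_temp - skin_temp) - q_dry - e_sk    # W/m^2 into skin

  list(core_flux = core_flux, skin_flux = skin_flux,
       q_dry = q_dry, q_res = q_res, e_sk = e_sk, e_max = e_max,
       m_total = m_tot, m_shiv = m_shiv,
       skin_blood_flow = skbf, sweat_rate = m_sw * area)  # sweat_rate in g/h, whole body
}

#' Advance the two-node heat balance by one explicit-Euler step
#'
#' @param state a [thermo_state()].
#' @param ambient_temp ambient temperature, degC.
#' @param rh relative humidity, percent, in `[0, 100]`.
#' @param subject a [subject_model()].
#' @param dt time step, seconds, in `(0, 300]`.
#' @return The updated `thermo_state`; `cumulative_sweat` is incremented by
#'   the regulatory sweat secreted during the step.
#' @export
step_heat_balance <- function(state, ambient_temp, rh, subject, dt = 60) {
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0 || dt > 300) {
    stopf("step_heat_balance: dt must be in (0, 300] seconds")
  }
  if (is.na(rh) || rh < 0 || rh > 100) {
    stopf("step_heat_balance: rh must be in [0, 100]")
  }
  cn <- .thermo_const
  if (state$core_temp < cn$core_bounds[1] || state$core_temp > cn$core_bounds[2] ||
      state$skin_temp < cn$skin_bounds[1] || state$skin_temp > cn$skin_bounds[2]) {
    stopf("simulation instability at %s: core %.2f degC, skin %.2f degC outside validity envelope",
          format(state$time), state$core_temp, state$skin_temp)
  }
  fl <- two_node_fluxes(state$core_temp, state$skin_temp, ambient_temp, rh, subject)
  area <- subject$body_surface_area
  state$core_temp <- state$core_temp + fl$core_flux * area / subject$core_heat_capacity * dt
  state$skin_temp <- state$skin_temp + fl$skin_flux * area / subject$skin_heat_capacity * dt
  state$cumulative_sweat <- state$cumulative_sweat + fl$sweat_rate * dt / 3600
  if (!is.na(state$time[1])) state$time <- state$time + dt
  state
}

# Internal vectorized integrator over one contiguous season.
# times: POSIXct of weather samples; temp/rh: vectors. Returns list with the
# daily summary data.frame and (optionally) the full trajectory.
simulate_one_season <- function(times, temp, rh, subject, dt, keep_trajectory) {
  cn <- .thermo_const
  gaps <- diff(as.numeric(times))
  if (any(gaps <= 0)) stopf("simulate_season: timestamps must be strictly increasing")
  if (any(gaps > 3 * 3600)) {
    stopf("simulate_season: gap of %.1f h in weather series exceeds 3 h", max(gaps) / 3600)
  }
  t0 <- as.numeric(times[1])
  t1 <- as.numeric(times[length(times)])
  step_t <- seq(t0, t1, by = dt)
  amb <- approx(as.numeric(times), temp, xout = step_t)$y
  hum <- clip(approx(as.numeric(times), rh, xout = step_t)$y, 0, 100)

  n <- length(step_t)
  core <- numeric(n); skin <- numeric(n); sweat_rate <- numeric(n)
  tc <- subject$core_setpoint; ts <- subject$skin_setpoint
  cum_sweat <- 0
  area <- subject$body_surface_area
  c_core <- subject$core_heat_capacity / area   # J/(K m^2)
  c_skin <- subject$skin_heat_capacity / area
  cum <- numeric(n)
  for (i in seq_len(n)) {
    if (tc < cn$core_bounds[1] || tc > cn$core_bounds[2] ||
        ts < cn$skin_bounds[1] || ts > cn$skin_bounds[2]) {
      stopf("simulation instability at %s: core %.2f degC, skin %.2f degC outside validity envelope",
            format(as.POSIXct(step_t[i], origin = "1970-01-01", tz = "UTC")), tc, ts)
    }
    fl <- two_node_fluxes(tc, ts, amb[i], hum[i], subject)
    core[i] <- tc; skin[i] <- ts; sweat_rate[i] <- fl$sweat_rate
    cum_sweat <- cum_sweat + fl$sweat_rate * dt / 3600
    cum[i] <- cum_sweat
    tc <- tc + fl$core_flux / c_core * dt
    ts <- ts + fl$skin_flux / c_skin * dt
  }
  stamp <- as.POSIXct(step_t, origin = "1970-01-01", tz = "UTC")
  day <- factor(as.Date(stamp, tz = "UTC"))  # levels sort in date order
  inc <- pmax(0, core - subject$core_setpoint)
  daily <- data.frame(
    date = as.Date(levels(day)),
    peak_core_increase_c = as.numeric(tapply(inc, day, max)),
    total_sweat_g = as.numeric(tapply(sweat_rate, day, sum)) * dt / 3600,
    row.names = NULL
  )
  traj <- NULL
  if (keep_trajectory) {
    traj <- data.frame(time = stamp, core_temp = core, skin_temp = skin,
                       ambient_temp = amb, rh = hum, sweat_rate = sweat_rate,
                       cumulative_sweat = cum)
  }
  list(daily = daily, trajectory = traj)
}

#' Simulate thermophysiological response over one or more seasons
#'
#' Integrates the two-node model continuously across each season (no daily
#' reset), linearly interpolating the hourly weather to the integration step.
#' Seasons separated by more than 3 h are integrated independently, each
#' starting from setpoint conditions.
#'
#' @param weather a `weather_series` (see [generate_weather()] or
#'   [read_weather()]): columns `timestamp`, `temp_c`, `rh_pct`.
#' @param subject a [subject_model()].
#' @param dt integration step, seconds (explicit Euler; default 60 s; halving
#'   `dt` changes daily peak core increase by well under 0.01 degC).
#' @param keep_trajectory if `TRUE`, attach the full state trajectory of the
#'   last season as attribute `"trajectory"`.
#' @return A data frame of class `thermo_daily` with columns `date`,
#'   `peak_core_increase_c` (daily maximum of core temperature above its
#'   setpoint, floored at 0) and `total_sweat_g` (daily regulatory sweat).
#' @export
simulate_season <- function(weather, subject = subject_model(), dt = 60,
                            keep_trajectory = FALSE) {
  if (!all(c("timestamp", "temp_c", "rh_pct") %in% names(weather))) {
    stopf("simulate_season: weather must have columns timestamp, temp_c, rh_pct")
  }
  if (dt <= 0 || dt > 300) stopf("simulate_season: dt must be in (0, 300] seconds")
  times <- weather$timestamp
  ord <- order(times)
  times <- times[ord]
  temp <- weather$temp_c[ord]; rh <- weather$rh_pct[ord]
  # split into seasons at multi-month breaks; shorter gaps are data holes
  # and are rejected inside simulate_one_season (> 3 h contract)
  brk <- c(0, cumsum(diff(as.numeric(times)) > 30 * 86400))
  out <- NULL; traj <- NULL
  for (b in unique(brk)) {
    sel <- brk == b
    res <- simulate_one_season(times[sel], temp[sel], rh[sel], subject, dt, keep_trajectory)
    out <- rbind(out, res$daily)
    traj <- res$trajectory
  }
  structure(out, class = c("thermo_daily", "data.frame"),
            trajectory = traj, dt = dt)
}

#' Steady-state heat-balance residual
#'
#' Conservation check on a simulated trajectory: at the state indexed by
#' `at` (default the final state), the imbalance between metabolic heat
#' production and the sum of respiratory, dry and evaporative losses. For a
#' converged constant-ambient run this equals the (near-zero) rate of heat
#' storage; mid-transient it equals the instantaneous storage rate.
#'
#' @param trajectory trajectory data frame (attribute `"trajectory"` of
#'   [simulate_season()] run with `keep_trajectory = TRUE`).
#' @param subject the [subject_model()] used for the run.
#' @param at row index at which to evaluate (default: last row).
#' @return Residual in W (whole body).
#' @export
heat_balance_residual <- function(trajectory, subject, at = nrow(trajectory)) {
  if (is.null(trajectory) || nrow(trajectory) < 1L) {
    stopf("heat_balance_residual: empty trajectory")
  }
  row <- trajectory[at, ]
  fl <- two_node_fluxes(row$core_temp, row$skin_temp, row$ambient_temp, row$rh, subject)
  area <- subject$body_surface_area
  abs(fl$m_total - fl$q_res - fl$q_dry - fl$e_sk) * area
}
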