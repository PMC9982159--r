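# Two-stage iterative estimation of {a, l, f, g} per location class,
# leave-one-out cross-validation by year, and the adaptation-window scan.
# The default stage objective is ordinary least squares on daily counts,
#   SSE = sum_t ( y_t - max(0, a (exp(k_t u_t) + l) S) )^2,  k_t = f A_t + g;
# a Poisson-deviance objective (the matched likelihood for Poisson counts)
# is available behind the config.

#' Fitting configuration for one location class
#'
#' Policies follow the published parameter structure: `l` is free only for
#' average-temperature inputs (thermophysiological inputs pin `l = -1` so
#' that estimates converge to zero at zero heat load), and `f` is absent for
#' outdoor thermophysiological inputs.
#'
#' @param input_kind model input kind.
#' @param location `"indoor"` or `"outdoor"`.
#' @param J adaptation window, days.
#' @param l_policy `"free"` or `"fixed"` (at -1). Default: `"free"` for
#'   average temperature, `"fixed"` otherwise.
#' @param f_policy `"free"` or `"absent"`. Default: `"absent"` for outdoor
#'   thermophysiological inputs, `"free"` otherwise.
#' @param objective `"ols"` (ordinary least squares on daily counts, the
#'   default) or `"poisson"` (Poisson deviance; the efficient choice when
#'   counts are Poisson).
#' @param weight_shape adaptation weight shape.
#' @param max_iterations maximum outer iterations of the two-stage loop.
#' @param convergence_tol relative parameter-change tolerance.
#' @param epsilon_warm additive constant in the log-linear warm start.
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(input_kind = c("average_temperature", "sweating",
                                      "core_temperature_increase"),
                       location = c("indoor", "outdoor"),
                       J = 40,
                       l_policy = NULL, f_policy = NULL,
                       objective = c("ols", "poisson"),
                       weight_shape = "linear_decreasing",
                       max_iterations = 100, convergence_tol = 1e-8,
                       epsilon_warm = 0.1) {
  input_kind <- match.arg(input_kind)
  location <- match.arg(location)
  objective <- match.arg(objective)
  thermo <- input_kind != "average_temperature"
  l_policy <- l_policy %||% if (thermo) "fixed" else "free"
  f_policy <- f_policy %||% if (thermo && location == "outdoor") "absent" else "free"
  if (!l_policy %in% c("free", "fixed")) stopf("fit_config: bad l_policy")
  if (!f_policy %in% c("free", "absent")) stopf("fit_config: bad f_policy")
  if (max_iterations < 1) stopf("fit_config: max_iterations must be >= 1")
  if (convergence_tol <= 0) stopf("fit_config: convergence_tol must be > 0")
  if (objective == "poisson" && l_policy == "free") {
    stopf("fit_config: the poisson objective supports only the fixed-l policy")
  }
  structure(list(input_kind = input_kind, location = location, J = as.integer(J),
                 l_policy = l_policy, f_policy = f_policy, objective = objective,
                 weight_shape = weight_shape,
                 max_iterations = as.integer(max_iterations),
                 convergence_tol = convergence_tol,
                 epsilon_warm = epsilon_warm),
            class = "fit_config")
}

# Assemble usable fitting rows for one location class: observed counts y,
# exponent input u, adaptation average A, population risk sum S.
prepare_fit_data <- function(counts, exposure, pop, cfg,
                             consts = age_risk_constants()) {
  cls <- risk_class_params(a = 1, l = if (cfg$l_policy == "fixed") -1 else 0,
                           f = if (cfg$f_policy == "absent") NA else 0,
                           g = 0, input_kind = cfg$input_kind, J = cfg$J,
                           weight_shape = cfg$weight_shape)
  mi <- class_model_inputs(exposure, cls, cfg$location)
  m <- match(counts$date, exposure$date)
  if (any(is.na(m))) stopf("prepare_fit_data: counts dates missing from exposure")
  y <- counts[[cfg$location]]
  u <- mi$u[m]; A <- mi$A[m]
  ok <- !is.na(y) & !is.na(u) & !is.na(A)
  if (sum(ok) < 10L) stopf("prepare_fit_data: fewer than 10 usable days")
  list(y = y[ok], u = u[ok], A = A[ok],
       S = population_risk_sum(pop, consts),
       year = counts$season[ok], date = counts$date[ok])
}

# Daily model means with the floor rule applied, matching estimate_series.
model_mean <- function(u, A, S, a, l, f, g) {
  f <- if (is.na(f)) 0 else f
  pmax(0, a * (exp(pmin((f * A + g) * u, 600)) + l) * S)
}

# Value of the fitting objective for floored model means mu:
# "ols" is the residual sum of squares; "poisson" the Poisson deviance.
obj_value <- function(y, mu, objective) {
  if (objective == "ols") return(sum((y - mu)^2))
  mu <- pmax(mu, 1e-12)
  2 * sum(ifelse(y > 0, y * log(y / mu), 0) - (y - mu))
}

sse_objective <- function(y, u, A, S, a, l, f, g, objective = "ols") {
  obj_value(y, model_mean(u, A, S, a, l, f, g), objective)
}

# Stage 1: (a, l) given fixed per-day k, respecting the floor rule via an
# active set: days whose prediction is floored at 0 contribute a
# parameter-independent residual and drop out of the estimating equations.
# Model: y ~ a*E + (a l)*S with E = exp(k u) S.
# "ols" solves the normal equations; "poisson" uses the closed-form MLE
# a = sum(y)/sum(z) available under the fixed-l policy.
stage_scale_offset <- function(y, u, S, k, l_policy, objective = "ols") {
  E <- exp(pmin(k * u, 600)) * S
  n <- length(y)
  solve_on <- function(act) {
    Ea <- E[act]; ya <- y[act]
    if (l_policy == "fixed") {
      z <- Ea - S
      pos <- z > 0
      if (!any(pos) || sum(z[pos]^2) <= .Machine$double.eps) {
        if (all(y == 0)) return(list(a = 0, l = -1, flag = "unidentifiable"))
        stopf("fit_scale_offset: degenerate design (constant exposure)")
      }
      a <- if (objective == "poisson") {
        sum(ya[pos]) / sum(z[pos])
      } else {
        sum(ya[pos] * z[pos]) / sum(z[pos]^2)
      }
      if (a <= 0) return(list(a = 0, l = -1, flag = "clamped"))
      list(a = a, l = -1, flag = "ok")
    } else {
      mE <- mean(Ea); vE <- sum((Ea - mE)^2)
      if (vE <= .Machine$double.eps * max(1, mE^2)) {
        stopf("fit_scale_offset: degenerate design (constant exposure)")
      }
      a <- sum((ya - mean(ya)) * (Ea - mE)) / vE
      flag <- "ok"
      if (!is.finite(a) || a <= 0) {
        a <- 1e-12
        flag <- "clamped"
      }
      c0 <- mean(ya) - a * mE
      list(a = a, l = c0 / (a * S), flag = flag)
    }
  }
  act <- rep(TRUE, n)
  res <- solve_on(act)
  for (it in seq_len(50)) {
    if (res$a <= 0) break
    new_act <- res$a * (E + res$l * S) > 0
    if (!any(new_act)) break
    if (identical(new_act, act)) break
    act <- new_act
    res <- solve_on(act)
  }
  res
}

# Stage 2 update of (f, g) (or g alone). For every candidate (f, g) the
# scale and offset are re-determined first by the closed-form stage-1 solve
# (variable projection), preserving the "(a, l) first, then (f, g)" order
# while keeping the alternation convergent. The adaptation average is
# standardized internally for conditioning. Returns the minimizing (f, g)
# together with the projected (a, l).
stage_adaptation <- function(y, u, A, S, f0, g0, f_policy, l_policy,
                             objective = "ols",
                             a_fixed = NULL, l_fixed = NULL) {
  fixed_al <- !is.null(a_fixed)
  big <- 1e300
  project <- function(k) {
    if (fixed_al) return(list(a = a_fixed, l = l_fixed, flag = "ok"))
    tryCatch(stage_scale_offset(y, u, S, k, l_policy, objective),
             error = function(e) NULL)
  }
  eval_obj <- function(k) {
    ku <- k * u
    if (any(!is.finite(ku)) || max(ku) > 600) return(big)  # overflow guard
    al <- project(k)
    if (is.null(al)) return(big)  # degenerate probe (e.g. k ~ 0)
    obj_value(y, pmax(0, al$a * (exp(ku) + al$l) * S), objective)
  }
  if (f_policy == "absent") {
    # One-dimensional search in g. The floor rule makes k <= 0 a flat
    # plateau of the objective, so bracket the minimum on a grid over the
    # admissible range (k * max(u) bounded away from overflow) first, then
    # polish with a golden-section/parabolic search in the bracket.
    g_hi <- 600 / max(abs(u))
    grid <- unique(sort(c(g0, seq(-0.02, 1, length.out = 200) * g_hi)))
    vals <- vapply(grid, function(g) eval_obj(rep(g, length(u))), numeric(1))
    i <- which.min(vals)
    lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
    opt <- stats::optimize(function(g) eval_obj(rep(g, length(u))),
                           lower = lo, upper = hi, tol = 1e-12)
    g_best <- if (opt$objective <= vals[i]) opt$minimum else grid[i]
    al <- project(rep(g_best, length(u)))
    return(list(f = NA_real_, g = g_best, a = al$a, l = al$l, flag = al$flag))
  }
  mA <- mean(A); sA <- sd(A)
  if (sA <= .Machine$double.eps * max(1, abs(mA))) {
    stopf("fit_adaptation: constant adaptation average, f unidentifiable")
  }
  As <- (A - mA) / sA
  # k = fs*As + gs  with  f = fs/sA, g = gs - fs*mA/sA
  obj <- function(p) eval_obj(p[1] * As + p[2])
  gr <- function(p) {
    # envelope: at the projected (a, l) the partial gradient in (f, g) is exact
    k <- p[1] * As + p[2]
    k <- pmin(k, 600 / pmax(abs(u), 1e-9))  # keep line-search probes finite
    al <- project(k)
    if (is.null(al)) return(c(0, 0))
    a <- al$a; l <- al$l
    e <- exp(k * u)
    pred <- a * (e + l) * S
    on <- pred > 0
    jbase <- a * S * e * u
    if (objective == "ols") {
      r <- y - pmax(0, pred)
      c(-2 * sum(r[on] * (jbase * As)[on]), -2 * sum(r[on] * jbase[on]))
    } else {
      mu <- pmax(pred, 1e-12)
      w <- 2 * (1 - y / mu)
      c(sum((w * jbase * As)[on]), sum((w * jbase)[on]))
    }
  }
  p0 <- c(f0 * sA, g0 + f0 * mA)
  opt <- optim(p0, obj, gr, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-15))
  # Levenberg-Marquardt / Fisher-scoring polish: fast local convergence
  p <- opt$par
  cur <- obj(p)
  lambda <- 1e-6
  for (lm_it in seq_len(200)) {
    k <- p[1] * As + p[2]
    al <- project(pmin(k, 600 / pmax(abs(u), 1e-9)))
    if (is.null(al)) break
    a <- al$a; l <- al$l
    e <- exp(pmin(k * u, 600))
    pred <- a * (e + l) * S
    r <- y - pmax(0, pred)
    jbase <- ifelse(pred > 0, a * S * e * u, 0)
    J <- cbind(jbase * As, jbase)          # d(pred)/d(fs, gs); 0 where floored
    if (objective == "poisson") {
      w <- 1 / pmax(pred, 1e-6)            # Fisher weights
      JtJ <- crossprod(J, J * w)
      Jtr <- crossprod(J, r * w)
    } else {
      JtJ <- crossprod(J)
      Jtr <- crossprod(J, r)
    }
    step_ok <- FALSE
    for (try_it in seq_len(30)) {
      delta <- tryCatch(solve(JtJ + lambda * diag(diag(JtJ) + 1e-30), Jtr),
                        error = function(e) NULL)
      if (is.null(delta)) { lambda <- lambda * 10; next }
      p_new <- p + as.numeric(delta)
      new <- obj(p_new)
      if (is.finite(new) && new <= cur) {
        step_ok <- TRUE
        improved <- (cur - new) > 1e-14 * (cur + 1e-300)
        moved <- max(abs(p_new - p) / (abs(p) + 1e-12)) > 1e-13
        p <- p_new; cur <- new
        lambda <- max(lambda / 10, 1e-12)
        if (!improved || !moved) step_ok <- FALSE  # converged
        break
      }
      lambda <- lambda * 10
    }
    if (!step_ok) break
  }
  al <- project(p[1] * As + p[2])
  list(f = p[1] / sA, g = p[2] - p[1] * mA / sA,
       a = al$a, l = al$l, flag = al$flag)
}

#' Fit the scale and offset parameters (a, l) with k fixed
#'
#' First stage of the two-stage procedure: with the adaptation coefficient
#' held fixed, the model is linear in `a` and `a*l`, so the stage minimizer
#' is closed form. Under the fixed-l policy `l` is pinned at -1.
#'
#' @param counts a `daily_counts` data frame.
#' @param exposure an `exposure_series`.
#' @param pop an `age_composition`.
#' @param k_fixed adaptation coefficient: scalar, or vector over the usable
#'   fitting days.
#' @param cfg a [fit_config()].
#' @return List with elements `a`, `l` and `flag` (`"ok"`,
#'   `"unidentifiable"` or `"clamped"`).
#' @export
fit_scale_offset <- function(counts, exposure, pop, k_fixed, cfg) {
  dat <- prepare_fit_data(counts, exposure, pop, cfg)
  k <- rep(k_fixed, length.out = length(dat$y))
  stage_scale_offset(dat$y, dat$u, dat$S, k, cfg$l_policy, cfg$objective)
}

#' Fit the adaptation parameters (f, g) with (a, l) fixed
#'
#' Second stage: minimizes the same objective over `(f, g)` (or `g` alone
#' when `f` is absent) with `k_t = f A_t + g` and `(a, l)` held at the
#' values from the previous stage.
#'
#' @inheritParams fit_scale_offset
#' @param a,l scale and offset from the previous stage.
#' @param start optional starting values `c(f, g)`.
#' @return List with elements `f` (`NA` when absent) and `g`.
#' @export
fit_adaptation <- function(counts, exposure, pop, a, l, cfg, start = NULL) {
  dat <- prepare_fit_data(counts, exposure, pop, cfg)
  # With (a, l) known, each positive-count day gives a direct estimate of
  # k_t = log(y_t/(aS) - l)/u_t; regressing those on A_t is an excellent
  # start for the local optimizer.
  st <- start
  if (is.null(st) && a > 0) {
    arg <- dat$y / (a * dat$S) - l
    ok <- arg > 0 & abs(dat$u) > 1e-9
    if (sum(ok) >= 3L) {
      kh <- log(arg[ok]) / dat$u[ok]
      if (cfg$f_policy == "absent" || sd(dat$A[ok]) == 0) {
        st <- c(f = 0, g = mean(kh))
      } else {
        cf <- coef(lm(kh ~ dat$A[ok]))
        st <- c(f = unname(cf[2]), g = unname(cf[1]))
      }
    }
  }
  st <- st %||% warm_start(dat, cfg)
  res <- stage_adaptation(dat$y, dat$u, dat$A, dat$S,
                          f0 = if (cfg$f_policy == "absent") 0 else st[["f"]],
                          g0 = st[["g"]], cfg$f_policy, cfg$l_policy,
                          cfg$objective, a_fixed = a, l_fixed = l)
  list(f = res$f, g = res$g)
}

# Log-linear warm start: with l at its policy value and f = 0, regress
# log(y/S + eps) on u to initialize g (slope) and a (exp(intercept)).
warm_start <- function(dat, cfg) {
  z <- log(dat$y / dat$S + cfg$epsilon_warm)
  fit <- lm(z ~ dat$u)
  g0 <- max(coef(fit)[[2]], 1e-8)
  a0 <- exp(coef(fit)[[1]])
  c(a = a0, f = 0, g = g0)
}

#' Two-stage iterative fit for one location class
#'
#' Alternates the closed-form (a, l) stage and the nonlinear (f, g) stage
#' until the maximum relative parameter change drops below the tolerance.
#' The stage objective is non-increasing across iterations; if the loop
#' exhausts `max_iterations`, the best-objective iterate is returned with
#' `converged = FALSE`.
#'
#' @inheritParams fit_scale_offset
#' @param cfg a [fit_config()].
#' @return List of class `fit_iterative`: `parameters` (a, l, f, g),
#'   `iterations`, `converged`, `objective_trace`, `flag`, `cfg`.
#' @export
fit_iterative <- function(counts, exposure, pop, cfg) {
  dat <- prepare_fit_data(counts, exposure, pop, cfg)
  st <- warm_start(dat, cfg)
  f <- if (cfg$f_policy == "absent") NA_real_ else 0
  g <- st[["g"]]
  a <- st[["a"]]; l <- -1
  trace <- numeric(0)
  best <- NULL
  converged <- FALSE
  iterations <- 0L
  flag <- "ok"
  for (it in seq_len(cfg$max_iterations)) {
    iterations <- it
    k <- adaptation_coefficient(f, g, dat$A)
    s1 <- stage_scale_offset(dat$y, dat$u, dat$S, k, cfg$l_policy, cfg$objective)
    flag <- s1$flag
    if (s1$flag == "unidentifiable") {
      a <- 0; l <- s1$l
      trace <- c(trace, sse_objective(dat$y, dat$u, dat$A, dat$S, a, l, f, g,
                                      cfg$objective))
      converged <- TRUE
      break
    }
    s2 <- stage_adaptation(dat$y, dat$u, dat$A, dat$S,
                           f0 = if (is.na(f)) 0 else f, g0 = g,
                           cfg$f_policy, cfg$l_policy, cfg$objective)
    obj <- sse_objective(dat$y, dat$u, dat$A, dat$S, s2$a, s2$l, s2$f, s2$g,
                         cfg$objective)
    trace <- c(trace, obj)
    old <- c(a = a, l = l, f = if (is.na(f)) 0 else f, g = g)
    a <- s2$a; l <- s2$l; f <- s2$f; g <- s2$g
    new <- c(a = a, l = l, f = if (is.na(f)) 0 else f, g = g)
    if (is.null(best) || obj <= best$obj) {
      best <- list(obj = obj, a = a, l = l, f = f, g = g)
    }
    rel <- max(abs(new - old) / (abs(new) + 1e-12))
    if (it > 1L && rel < cfg$convergence_tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged && !is.null(best)) {
    a <- best$a; l <- best$l; f <- best$f; g <- best$g
  }
  structure(list(parameters = list(a = a, l = l, f = f, g = g),
                 iterations = iterations, converged = converged,
                 objective_trace = trace, flag = flag, cfg = cfg),
            class = "fit_iterative")
}

# risk_class_params from a fit_iterative result.
fitted_class_params <- function(fit) {
  p <- fit$parameters
  cfg <- fit$cfg
  risk_class_params(a = max(p$a, .Machine$double.xmin), l = p$l, f = p$f, g = p$g,
                    input_kind = cfg$input_kind, J = cfg$J,
                    weight_shape = cfg$weight_shape)
}

#' Leave-one-out cross-validation by year
#'
#' For each year, fits both location classes on all remaining years pooled
#' and predicts the held-out year. The reported parameter set is the
#' arithmetic mean of the per-held-out-year sets.
#'
#' @param counts a `daily_counts` data frame spanning at least 3 seasons.
#' @param exposure the matching `exposure_series`.
#' @param pop an `age_composition`.
#' @param cfg_indoor,cfg_outdoor [fit_config()] per location class.
#' @param consts an [age_risk_constants()].
#' @return List of class `fit_result`: `per_year` (list, per held-out year:
#'   `params`, `fit_indoor`, `fit_outdoor`), `averaged` (mean
#'   [risk_parameters()]), `predictions` (held-out `date`, `year`, observed
#'   and predicted counts), `r2_by_year`, `converged`.
#' @export
loocv_by_year <- function(counts, exposure, pop, cfg_indoor, cfg_outdoor,
                          consts = age_risk_constants()) {
  years <- sort(unique(counts$season))
  if (length(years) < 3L) stopf("loocv_by_year: need at least 3 years")
  per_year <- list()
  preds <- NULL
  r2 <- NULL
  for (y in years) {
    train <- counts[counts$season != y, , drop = FALSE]
    test <- counts[counts$season == y, , drop = FALSE]
    fit_in <- try(fit_iterative(train, exposure, pop, cfg_indoor), silent = TRUE)
    fit_out <- try(fit_iterative(train, exposure, pop, cfg_outdoor), silent = TRUE)
    if (inherits(fit_in, "try-error") || inherits(fit_out, "try-error")) {
      warning(sprintf("loocv_by_year: fold %s failed and was excluded", y))
      next
    }
    params <- risk_parameters(fitted_class_params(fit_in),
                              fitted_class_params(fit_out), consts)
    est <- estimate_series(exposure[exposure$season == y, , drop = FALSE],
                           pop, params)
    m <- match(test$date, est$date)
    ok <- !is.na(m)
    pr <- data.frame(date = test$date[ok], year = y,
                     obs_indoor = test$indoor[ok], obs_outdoor = test$outdoor[ok],
                     obs_total = test$total[ok],
                     y_in = est$y_in[m[ok]], y_out = est$y_out[m[ok]],
                     y = est$y[m[ok]])
    preds <- rbind(preds, pr)
    r2 <- rbind(r2, data.frame(
      year = y,
      r2_total = r_squared(pr$obs_total, pr$y),
      r2_indoor = r_squared(pr$obs_indoor, pr$y_in),
      r2_outdoor = r_squared(pr$obs_outdoor, pr$y_out)
    ))
    per_year[[as.character(y)]] <- list(params = params,
                                        fit_indoor = fit_in, fit_outdoor = fit_out)
  }
  if (length(per_year) < 2L) stopf("loocv_by_year: fewer than 2 usable folds")
  averaged <- average_parameters(lapply(per_year, `[[`, "params"))
  structure(list(per_year = per_year, averaged = averaged,
                 predictions = preds, r2_by_year = r2,
                 converged = all(vapply(per_year, function(p)
                   p$fit_indoor$converged && p$fit_outdoor$converged, logical(1)))),
            class = "fit_result")
}

#' Scan the adaptation-window length
#'
#' Re-runs the full cross-validated fit at each candidate window length `J`
#' (applied to both location classes) and reports the mean held-out R^2 per
#' class, supporting location of the accuracy plateau.
#'
#' @inheritParams loocv_by_year
#' @param J_values integer vector of candidate windows.
#' @return Data frame with columns `J`, `r2_indoor`, `r2_outdoor` (mean over
#'   years); candidate windows exceeding the available history are skipped
#'   with a warning.
#' @export
scan_adaptation_window <- function(counts, exposure, pop, cfg_indoor,
                                   cfg_outdoor, J_values,
                                   consts = age_risk_constants()) {
  out <- NULL
  max_season_len <- max(table(exposure$season))
  for (J in J_values) {
    if (J >= max_season_len - 5L) {
      warning(sprintf("scan_adaptation_window: J = %d exceeds available history, skipped", J))
      next
    }
    ci <- cfg_indoor; ci$J <- as.integer(J)
    co <- cfg_outdoor; co$J <- as.integer(J)
    res <- try(loocv_by_year(counts, exposure, pop, ci, co, consts), silent = TRUE)
    if (inherits(res, "try-error")) {
      warning(sprintf("scan_adaptation_window: J = %d failed, skipped", J))
      next
    }
    out <- rbind(out, data.frame(J = J,
                                 r2_indoor = mean(res$r2_by_year$r2_indoor),
                                 r2_outdoor = mean(res$r2_by_year$r2_outdoor)))
  }
  out
}
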