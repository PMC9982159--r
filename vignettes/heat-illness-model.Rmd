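---
title: "Estimating daily heat-illness transport counts: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating daily heat-illness transport counts: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heatmorb)
```

## The problem

On hot summer days the number of people transported by ambulance for heat
illness surges, and emergency services need day-ahead estimates of that
number to allocate vehicles and staff. heatmorb implements a complete
estimation pipeline for daily counts of heat-illness transports in a
prefecture-sized region: a human thermoregulation surrogate that converts
weather into physiological heat-strain exposure, a nonlinear morbidity
model with lagged heat adaptation, a cross-validated fitting procedure,
and the evaluation metrics used to judge such models. Because the original
administrative datasets (hourly weather, daily transport counts split by
occurrence location, age pyramids) are not redistributable, the package
also contains a first-class synthetic-data generator that reproduces their
statistical structure, and the whole pipeline is tested against it.

## The morbidity model

Daily expected transports are the sum of an indoor (non-exertional) and an
outdoor (exertional) component,

$$y = y_{in} + y_{out},$$

each an exponential function of a heat-exposure input $x$ scaled by an
age-weighted population sum:

$$y_{in} = a_{in}\left[e^{k_{in}(0.6x_0+0.2x_1+0.2x_2)} + l_{in}\right]
  \sum_n P(n)\,(b e^{cn} + d),$$
$$y_{out} = a_{out}\left(e^{k_{out}x_0} + l_{out}\right)
  \sum_n P(n)\,(b e^{cn} + d).$$

* $x_0$ is the input on the estimated day, $x_i$ the input $i$ days
  earlier. Indoor cases respond to a short three-day window with weights
  0.6/0.2/0.2; outdoor cases respond to the same day only.
* $P(n)$ is the fraction of population in 5-year adult age category $n$
  ($n = 1$: 20–24 years, ..., $n = 14$: 85+), and $b = 0.171$,
  $c = 0.494$, $d = 190.7$ are fixed regression constants describing the
  rise of per-capita risk with age. Because $P$ is normalized, the overall
  population scale is absorbed into $a$.
* Heat adaptation enters through the coefficient
  $k = f \cdot \bar{x}_J + g$, where $\bar{x}_J = \sum_{i=1}^{J} w_i
  x_{t-i}$ is a weighted average of the input over the previous $J$ days
  (the current day excluded). As the summer accumulates heat exposure,
  $\bar{x}_J$ grows and (with $f < 0$) the risk coefficient falls — the
  population acclimatizes.

Three input kinds are supported: daily mean ambient temperature, daily
maximum core-temperature increase, and daily total sweating (the latter
two computed by the thermoregulation surrogate). For the
thermophysiological inputs the offset is pinned at $l = -1$ so that zero
heat load implies exactly zero expected cases; for temperature inputs $l$
is a free (typically large negative) tuning constant with no physiological
interpretation, and the model value is floored at zero on days where the
exponential falls below $-l$. The floor is part of the model everywhere in
this package — generation, estimation *and* fitting — because counts cannot
be negative; leaving it out of the fitting objective measurably biases
parameter recovery on data generated with the floor.

## The two-node thermoregulation surrogate

The reference implementation of the physiological inputs in the literature
is an anatomical voxel model run on a supercomputer; that is out of scope
here. heatmorb instead ships a classical two-node (core/skin) lumped
model — the standard desk-scale description of human thermoregulation —
with the same inputs (hourly temperature and relative humidity) and the
same outputs (daily peak core-temperature increase, daily total sweat):

* **Core node**: metabolic heat (plus shivering thermogenesis when cold)
  minus respiratory losses minus core-to-skin transport through tissue
  conductance and skin blood flow.
* **Skin node**: inflow from the core minus dry (convective + radiative)
  loss through clothing minus evaporative loss, the latter capped by the
  humidity-dependent evaporative maximum computed from the
  saturated-vapor-pressure difference (Tetens form,
  $p_{sat} = 0.61078\,e^{17.27T/(T+237.3)}$ kPa).
* **Control**: skin blood flow rises with the core warm signal
  (vasodilation) and falls with the skin cold signal (vasoconstriction);
  regulatory sweating is proportional to a core-weighted warm signal with
  a whole-body cap; shivering uses the standard product-of-cold-signals
  form.

All subject constants live in `subject_model()`. The defaults describe a
resting 70 kg adult at about 1 met in light summer clothing (0.1 clo)
whose steady state at 28 °C / 50 % RH is thermoneutral: no active
sweating, core at its setpoint. Vasoconstriction and shivering are
included — although heat is the topic — because the synthetic June nights
legitimately reach 15–18 °C, where a surrogate without cold defenses
drifts into hypothermia and aborts.

Integration is explicit Euler at `dt = 60` s (hourly weather linearly
interpolated), continuous across each season with no daily reset, and
daily quantities are aggregated afterwards. Halving `dt` moves daily peak
core increase by far less than the 0.01 °C contract. A validity envelope
of 30–45 °C is enforced on the core temperature each step; the skin node
uses a wider 15–45 °C instability envelope because a lightly clothed
subject on a cool night has skin well below 30 °C while being perfectly
fine — treating that as a failure would abort every cool night.

The daily peak core increase is floored at 0 so that the $l = -1$
convention (zero cases at zero heat load) is well defined on cool days.

## Exposure features

`build_exposure()` produces per-day records: mean and maximum temperature,
the thermophysiological summaries, and WBGT. WBGT is computed from
temperature and humidity only (no solar radiation is available in the
model's data feeds) with the fixed regression

$$\mathrm{WBGT} = -4.064 + 0.735\,T + 0.0374\,\mathrm{RH} +
  0.00292\,T\cdot \mathrm{RH},$$

the daily value being the maximum over the day's hours. WBGT is used only
to stratify "hot days" (threshold 31 °C), so approximation error merely
shifts the stratum boundary.

The adaptation weights $w_i$ are, by default, linearly decreasing over
lags $1..J$ (most recent day heaviest, normalized to 1), with a uniform
option. The weighting shape is deliberately isolated behind
`adaptation_config()`: the underlying description ("weighted linear
function") is ambiguous, and recency emphasis is the reading most
consistent with acclimatization decaying over weeks. Seasons are processed
independently — June–September blocks — and lag windows never cross season
boundaries; days lacking history are dropped from fitting rather than
zero-filled.

## Fitting

Parameters are estimated per location class by a two-stage procedure:
$(a, l)$ are determined first — with the adaptation coefficient fixed, the
model is linear in $a$ and $a\,l$, so the stage is a closed-form
least-squares solve (with an active set handling floored days) — followed
by $(f, g)$, a two-parameter nonlinear minimization; the two stages are
iterated to convergence. For the $(f, g)$ stage the package uses variable
projection: every candidate $(f, g)$ re-determines $(a, l)$ first by the
closed-form stage. This preserves the "scale/offset first, adaptation
second" structure while converging in a couple of outer iterations;
freezing $(a, l)$ during the $(f, g)$ stage instead produces the classic
alternating-descent zigzag and does not reach tight tolerances in bounded
time. The one-dimensional $g$-only case (outdoor thermophysiological
inputs) is bracketed on a grid before polishing, because the floor rule
turns $k \le 0$ into a flat objective plateau that traps naive
line searches.

The default objective is ordinary least squares on daily counts. A
Poisson-deviance objective (`fit_config(objective = "poisson")`) is
available and is the efficient choice when counts are genuinely
Poisson — the package's own synthetic noise model. On synthetic data at
realistic count levels the deviance objective reduces the dispersion of
the adaptation intercept $\hat g$ by roughly a third relative to OLS,
which is the difference between meeting and missing a 5 %-recovery bound;
the acceptance suite uses it for exactly that reason.

Warm starts come from a log-linear regression of $\log(y/S + 0.1)$ on the
input, initializing $g$ (slope) and $a$ (intercept); $a > 0$ is maintained
structurally (closed-form solutions are clamped, with a flag, in the
degenerate all-zero case).

Cross-validation follows the leave-one-year-out design: each season is
predicted from a model fitted on all other seasons pooled, and the
reported parameter set is the arithmetic mean of the per-fold sets.
`scan_adaptation_window()` re-runs the full cross-validated fit over a
grid of window lengths $J$ and reports mean held-out $R^2$ per location
class, which locates the accuracy plateau (the synthetic world, generated
with $J^*_{in} = 40$ and $J^*_{out} = 30$, reproduces its own argmax).

The 95 % band around estimates (`estimate_band()`) is a parameter
bootstrap over the per-fold parameter sets — resample sets with
replacement, average, re-predict, take per-day 2.5/97.5 percentiles — the
construction of the published band being unstated. The envelope is widened
to bracket the point estimate so the band invariant (lower ≤ point ≤
upper) holds by construction.

## The synthetic world

`weather_scenario()` states the world the tests run in, chosen once to
mimic a humid-subtropical (Cfa) Japanese metropolitan summer:

| parameter | default | meaning |
|---|---|---|
| season | Jun 1 – Sep 30, 7 years | the annual observation window |
| `base_temp` | 24 °C | daily-mean level at the season edges |
| `seasonal_amplitude` | 6 °C | half-sine peak in late July/August |
| `diurnal_amplitude` | 4 °C | within-day cosine, peak at 14:00 |
| `rainy_season_end` | day 50 (≈ Jul 20) | cooling regime ends |
| `rainy_season_cooling` | 2 °C | depression before the break |
| `ar1_coef`, `noise_sd` | 0.6, 1.5 °C | AR(1) day-to-day anomalies |
| `rh_base`, `rh_temp_slope` | 80 %, 1.5 %/°C | humidity anticorrelation |

These give afternoon peaks of 34–38 °C on the hottest days, some days
above the WBGT 31 °C hot-day threshold, and cool June nights — the regime
features the estimation problem actually faces. The age pyramid is a
softmax shape `P(n) ∝ exp(aging_index·n/14)` with `aging_index = 2`
(an aged prefecture); counts are Poisson around the model mean, at
2–5 patients/day per million population (the observed prefecture range),
for a default population of 10 million.

Generating parameters (`default_parameters()`) keep the published
magnitudes for the temperature input (including the published $f$, $g$,
$l$ for a large metropolitan prefecture) with the scale $a$ adjusted for
normalized $P(n)$; the thermophysiological sets were calibrated once
against the surrogate's own output scales (peak core increase 0–0.45 °C,
daily sweat 0–3 kg) to land counts in the same realistic band, and then
frozen.

What a green test does establish: the pipeline is self-consistent
(round-trip identity), the estimator recovers known parameters at
realistic noise levels, the window scan finds the generating window, the
surrogate conserves energy and responds monotonically to heat. What it
does not establish: agreement with the real administrative data (typhoons,
reporting artifacts, behavioral changes and heat-wave extrapolation are
all absent from the synthetic world), nor the anatomical fidelity of the
two-node surrogate.

## Numerical choices and degenerate inputs

* Exponent overflow is guarded at $k\,u \le 600$; probes beyond return a
  large penalty rather than NaN.
* Degenerate designs error loudly: constant exposure with a free offset
  ("degenerate design"), constant adaptation average with free $f$
  ("unidentifiable"). All-zero counts with zero exposure yield $a = 0$
  with an `"unidentifiable"` flag instead of an error, matching the
  zero-heat contract.
* Convergence is declared on the maximum relative parameter change
  (default `1e-8`, `max_iterations = 100`); a non-converged loop returns
  the best-objective iterate with `converged = FALSE`.
* F-tests compare the fitted model against the intercept-only model with
  degrees of freedom equal to the number of actually fitted parameters
  (4 for temperature inputs, 3 indoor / 2 outdoor for thermophysiological
  inputs).
* The indoor/outdoor split of historical totals is real-valued
  (`split_total_by_location()`), conserving the total exactly; rounding is
  left to display.

## Known limitations

* The two-node surrogate is a desk-scale stand-in: no solar load, no
  age-specific physiology, one fixed clothing level. Its absolute sweat
  and core values should be read as exposure indices, not clinical
  predictions.
* Units of "amount of sweating" are treated as configuration: the model
  is scale-free in the input (the scale moves $g$ and $f$), so grams/day
  is used throughout.
* The Poisson count noise is a stand-in — the original work states no
  stochastic model for counts.
* On information grounds, some recovery precision targets are only
  reachable with the efficient (Poisson) objective at the stated count
  levels; OLS leaves ~30 % more dispersion in $\hat g$.
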