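---
title: "Summit pressure and oxygen availability: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Summit pressure and oxygen availability: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thickair)
```

This vignette is the package's account of its science: what each model
assumes, why the defaults are what they are, what the synthetic data do
and do not emulate, and where the design was genuinely open.

## Hypsometric reconstruction

Within the troposphere, pressure falls exponentially with height at a
rate inversely proportional to the layer's virtual temperature. Over a
layer thin enough for that temperature to be treated as constant, log
pressure is linear in geopotential height, so two pressure levels
bracketing a target elevation determine a local gradient

$$\Gamma = \frac{\ln p_{\mathrm{lower}} - \ln p_{\mathrm{upper}}}{z_{\mathrm{upper}} - z_{\mathrm{lower}}},$$

and the target pressure is $p_1 e^{-\Gamma (z - z_1)}$. The assumptions
are (i) the bracketing layer is thin (here roughly 1,100 m between the
350 and 300 hPa surfaces), and (ii) the gridded heights are accurate.
Because the gradient is estimated locally per timestamp, temperature
variations enter through the level heights themselves; no separate
virtual-temperature correction is applied.

`reconstruct_summit_series()` chooses the two levels whose heights
straddle the summit. When the summit sits below the lowest level height
the lowest adjacent pair is used (minimal extrapolation distance); when
it sits above the topmost height by more than one level spacing the
timestamp is flagged missing rather than extrapolated blindly. A
comparison method, `interpolate_direct_series()`, interpolates pressure
linearly in height; ignoring the exponential profile biases it low by
roughly $p\,(\Gamma \Delta z)^2/8$ within a layer (≈0.8 hPa for the
default geometry), which is why the gradient method wins on every
fixture in the test suite.

The bias adjustment is a single constant offset, the mean of
(station − model) over the full overlap; the exact form of such
adjustments is an open choice, and a per-calendar-month variant is
available through `bias_adjustment(..., by_month = TRUE)`. Validation
statistics (MAE, mean bias, Pearson r) use pairwise-complete overlap
only; missing observations are never interpolated.

## Day-of-year climatology

Per-day mean/min/max across years are smoothed with a circular Gaussian
kernel so the curves are continuous across the new-year boundary. The
kernel width is not something a daily climatology pins down on its own;
the default σ = 7 days suppresses day-to-day sampling noise while
leaving the ≈16 hPa seasonal contrast intact, and it is exposed as
`sigma_days`. Feb 29 is folded into day 59, giving a fixed 365-day
axis. Smoothing each statistic with the same weights preserves the
min ≤ mean ≤ max ordering pointwise.

## The physiology layer

**VO2max.** Published measurements constrain the curve only at a handful
of pressures, so the package *defines* the summit-range curve by exact
interpolation of its anchors: a cubic $V(P)$ solving the linear system

- $V(333) = 16.2$ mL kg⁻¹ min⁻¹,
- $V(329) = 0.919\,V(340)$ (an 8.1 % reduction),
- $V(309) = 0.841\,V(329)$ (15.9 %),
- $V(309) = 0.760\,V(343)$ (24.0 %).

Ratio constraints are linear in the polynomial coefficients, so the
4×4 system is solved directly. The fitted cubic is verified strictly
increasing and positive on 300–345 hPa (it is); if an alternative anchor
set ever violated that, the model falls back to a monotone
piecewise-cubic interpolant through anchor-consistent nodes. Above
343 hPa the curve continues to sea level through a monotone Hermite
interpolant with nodes at the ICAO pressures of 3,169 m and 2,132 m
(76.0 % and 84.1 % of the sea-level 57 mL kg⁻¹ min⁻¹) — chosen so that
ICAO-equivalent elevations for those reductions are reproduced by
construction — and V(1013.25) = 57. The model refuses pressures below
300 hPa: nothing validates it there.

A single exponential in inspired pO2 cannot reproduce all three printed
ratio anchors simultaneously, which is the concrete reason an
interpolating curve was chosen over a parametric form.

**Climbing rate.** The minimal model consistent with the two printed
speed anchors is linear-above-overhead:
$\mathrm{rate} = k\,(V(P) - b)\cdot m_{\mathrm{ref}}/m$, with $b$ the
oxygen cost that buys no upward progress. Calibrating to
rate(343 hPa, 100 kg) = 3.5 m min⁻¹ and a 41.2 % reduction at 309 hPa
gives b ≈ 7.23 mL kg⁻¹ min⁻¹ and k ≈ 0.347; the 29.5 % reduction
between 329 and 309 hPa is then a parameter-free consistency check,
which the calibrated pair meets at 29.55 %. Rates floor at zero with a
`below_threshold` flag when $V(P) \le b$.

**Other conversions.** Inspired pO2 is the dry-air proportionality
0.2095 P (no water-vapour subtraction — none is specified for these
summit conditions). Apparent elevation converts pressure to the height
at which it would be met on a reference mean May day
(Γ = 1.4 × 10⁻⁴ m⁻¹ anchored at 333 hPa / 8,850 m), regardless of the
actual month — it is a communication device, not a forecast. The
oxygenless feasibility threshold is ≈302 hPa, representative of very fit
climbers (sea-level VO2max ≈ 57 mL kg⁻¹ min⁻¹); fitter individuals can
go lower, so the threshold is a parameter, not a law.

The standard ICAO formula at 8,850 m gives 314.3 hPa, while 313 hPa is
often quoted; the quoted value likely reflects a slightly different
summit elevation or a tabulated atmosphere. The package computes the
formula and leaves the discrepancy visible.

## Synthetic study conditions

The generator's defaults are the conditions the rest of the package is
tested under; they are fixed once, not tuned per test.

- **Seasonal cycle**: a single annual harmonic least-squares fitted to
  the twelve monthly normals (January 323 hPa through August 339 hPa,
  annual mean ≈331 hPa). The fitted second harmonic contributes under
  0.03 hPa and is dropped. Fit result: mean 331.2 hPa, amplitude
  8.3 hPa, maximum at day-of-year ≈214.
- **Weather noise**: AR(1) at the hourly step with coefficient 0.98 and
  a stationary standard deviation interpolated between 3.5 hPa
  (mid-January) and 1.2 hPa (mid-July). These values make the simulated
  winter monthly range roughly three times the monsoon range (≈20 vs
  ≈6 hPa), matching the observed contrast. The AR(1) form itself is an
  assumption — hourly pressure increments are not otherwise
  distributionally constrained.
- **Wave events**: two per winter, Gaussian troughs of 10 hPa depth and
  4-day full width at half maximum, centres uniform over a Dec 10–Feb 20
  window with at least 12 days of mutual separation. Because the
  monthly normals describe the climate *including* such events, the
  deterministic cycle is raised by the analytic expectation of the event
  anomaly, so realised January means still sit at ≈323 hPa. The events
  ride on a zonally traveling sinusoidal ridge–trough pattern
  (10 m s⁻¹, 6,000 km requested wavelength, snapped to an integer zonal
  wavenumber so the wave is continuous around the 28° N latitude
  circle), giving the transit-time estimator a known truth.
- **Station model**: truth extrapolated to 7,945 m plus a constant
  offset (0.5 hPa default), iid noise (0.2 hPa) and block-structured
  outages removing exactly `round(gap_fraction · n)` hours — blocks, not
  isolated hours, because station failures come in runs.
- **Ensemble**: 21 models, true sensitivities drawn from
  N(2.2, 0.35²) hPa °C⁻¹, a linear 0.25 °C/decade forcing path over
  1950–2100 with winter-amplified monthly response factors (mean 1
  across the year, so the annual-mean sensitivity is the drawn value and
  the annual-minimum sensitivity exceeds it, as expected when winters
  respond most).
- **Ascent catalog**: 10,068 ascents of which 208 oxygenless (the share
  prints as 2.1 %), months drawn from the observed May-dominated
  weights, and climb days drawn toward the 70th pressure percentile of
  their month via a Beta(7, 3) percentile target — emulating climbers'
  preference for high-pressure windows.

What the generator does **not** emulate: full four-dimensional
reanalysis physics, humidity, reanalysis inhomogeneity over time,
non-Gaussian pressure tails, coupling between the injected wave field
and the summit series beyond shared timing, and any real topography.
Passing tests therefore demonstrate that the *methods* recover known
structure under realistic statistics — not that real-archive results
(e.g. a 0.36 hPa station MAE or a 3.9-day median transit time) are
reproduced numerically; those require the external archives.

## Extremes

Events are the n globally lowest pressures under a greedy exclusion
window (default 10 days — event independence is not otherwise defined,
so the window is exposed). Anomalies for composites are taken against
the smoothed day-of-year mean. Transit times come from tracking the
phase of the dominant zonal harmonic (chosen from the time-averaged
amplitude spectrum, since a traveling wave cancels in the time-mean
profile); phase increments are unwrapped to within half a wavelength,
so the method is unambiguous while the pattern moves less than half a
wavelength per step (comfortably true at 6-hourly steps for observed
phase speeds). Events with incoherent phase increments (circular
concentration < 0.9) or no net movement are flagged and excluded from
summary medians.

## Trends and sensitivities

Theil-Sen slopes are medians of all pairwise slopes; pairs with
duplicate years are excluded. The uncertainty band is the 5th–95th
percentile of the raw pairwise-slope distribution — simple,
deterministic, and conservative (simulated coverage of a true trend at
the study's 41-year length is well above 90 %); a bootstrap variant is
available behind `ci = "bootstrap"`. Ensemble sensitivities regress
30-year running means (centred window, truncated ends) of the annual
statistic on equally smoothed global temperature, by ordinary least
squares per model, summarised by the ensemble median and 5th–95th
range. Constant smoothed temperature is a degenerate regressor: such
models are excluded with a warning, and an all-degenerate ensemble is an
error.

Projections are linear in the warming level and flagged beyond ±4.5 °C,
where the scenario range ends. Warming-equivalence is the inverse map
(target − current)/sensitivity; the two are exact mutual inverses, and
the tests hold them to that.

## Ascents

Ascent-day pressure is the daily mean over the local (UTC+5:45) day —
the actual summit hour is generally unrecorded — with an instantaneous
`summit_hour` variant (default 09:00 local, snapped to the nearest
series hour). Monthly-table percentages are computed by direct counting
over hourly values, and the climbing-mean percentile is the fraction of
the month's hours below the mean climbing pressure, which makes it
invariant to any strictly monotone transform of the series.

## Numerical choices and problem sizes

Tolerances: the hypsometric round-trip identity is asserted to
1e-9 hPa; calibration anchors to 1e-9; mutual-inverse identities to
1e-12. Degenerate inputs are flagged rather than silently handled:
equal-pressure layers (zero gradient), zero-variance validation series
(undefined r), constant smoothed temperature, unsustainable climbing
rates (zero with a flag), stationary waves (non-propagating).

The test suite runs the default study conditions at 41 years of hourly
data (≈359,000 points), a 21-model × 151-year monthly ensemble, and a
10,068-record catalog; recovery tests for event timing and phase speed
use a low-noise variant (0.2 hPa winter σ) of the same conditions so
the truth is identifiable to the stated ±6 h and ±10 % tolerances.
Trend-coverage checks use 200 seeded annual-scale replicates whose
interannual noise level is taken from the generated hourly climate.

## Known limitations

- The VO2max curve is exact interpolation of printed anchors, not a
  physiological model; between anchors its curvature is an artefact of
  the cubic, and below 300 hPa it is deliberately undefined.
- The climbing-rate overhead model is the minimal two-parameter choice;
  real climbers differ in economy, acclimatization and pacing.
- The constant bias adjustment assumes a height-independent,
  season-independent station offset.
- Synthetic recovery tolerances certify the estimators, not real-data
  accuracy; reanalysis and ensemble archives would be needed for the
  latter.
- Apparent elevation always references mean May conditions; in other
  seasons it answers "what would this pressure feel like in May", by
  design.
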