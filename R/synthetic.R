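#' Monthly-mean summit pressure normals (hPa)
#'
#' The twelve monthly means of reconstructed summit pressure used to pin
#' the synthetic seasonal cycle: a 323 hPa January minimum rising to
#' 339 hPa in the August monsoon around a 331 hPa annual mean.
#'
#' @return named numeric vector, Jan..Dec.
#' @export
summit_monthly_normals <- function() {
  stats::setNames(
    c(323, 323, 325, 329, 333, 337, 339, 339, 338, 333, 329, 326),
    month.abb
  )
}

#' Fit a first-harmonic seasonal cycle to monthly means
#'
#' Least-squares fit of `mean + amplitude * cos(2*pi*(doy - phase_day)/365.25)`
#' to twelve monthly means placed at month mid-points. The annual cycle of
#' summit pressure is close to a single harmonic; the second harmonic of
#' the default normals contributes under 0.03 hPa and is ignored.
#'
#' @param monthly twelve monthly means (Jan..Dec).
#' @return list with `mean`, `amplitude` (hPa) and `phase_day`
#'   (day of year of the seasonal maximum).
#' @export
fit_seasonal_cycle <- function(monthly = summit_monthly_normals()) {
  stopifnot(length(monthly) == 12)
  dim_days <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
  mid <- cumsum(dim_days) - dim_days / 2
  w <- 2 * pi * mid / 365.25
  fit <- stats::lm(monthly ~ cos(w) + sin(w))
  a <- stats::coef(fit)[2]
  b <- stats::coef(fit)[3]
  list(
    mean = as.numeric(stats::coef(fit)[1]),
    amplitude = as.numeric(sqrt(a^2 + b^2)),
    phase_day = as.numeric((atan2(b, a) / (2 * pi) * 365.25) %% 365.25)
  )
}

#' Configuration for the synthetic-data generator
#'
#' Defines every tunable of the synthetic study conditions: the period and
#' sampling step; the seasonal cycle of summit pressure (defaults fitted
#' to [summit_monthly_normals()], giving roughly 323 hPa in mid-January
#' and 339 hPa in mid-August); winter-amplified AR(1) weather noise;
#' injected wintertime wave events (traveling troughs with a known zonal
#' phase speed); the weather-station error model (constant offset, iid
#' noise, block gaps); the climate-model ensemble (per-model true
#' sensitivities in hPa per degree of smoothed global warming); and the
#' ascent-catalog model (month weights plus a high-pressure selection
#' bias). All randomness flows from `seed` via named per-stage substreams.
#'
#' @param start,end period covered (parsed as UTC).
#' @param step_hours sampling step of the summit series, hours.
#' @param summit_elevation metres.
#' @param seasonal_mean,seasonal_amplitude,seasonal_phase_day seasonal
#'   cycle parameters (hPa, hPa, day of year of the maximum).
#' @param ar1 hourly AR(1) coefficient of the weather noise.
#' @param sigma_winter,sigma_summer stationary noise standard deviation
#'   (hPa) in mid-winter / mid-summer; must satisfy
#'   `sigma_winter >= sigma_summer >= 0`.
#' @param events_per_winter injected low-pressure wave events per winter.
#' @param event_depth_hPa,event_duration_days trough depth and full width
#'   at half maximum of the injected events.
#' @param phase_speed_ms,wavelength_km zonal phase speed and wavelength of
#'   the traveling upper-level wave behind the events.
#' @param station_elevation,aws_offset_hPa,aws_sigma_hPa,aws_gap_fraction
#'   weather-station emulation: station height, constant instrument
#'   offset, iid observation noise, fraction of timestamps lost to
#'   outages (`0 <= gap < 1`).
#' @param n_models,sensitivity_mean,sensitivity_sd ensemble size and the
#'   distribution the per-model true sensitivities (hPa per degree C) are
#'   drawn from.
#' @param warming_rate_per_decade global-mean warming rate, degrees C per
#'   decade, of the ensemble forcing path.
#' @param ens_start_year,ens_end_year ensemble coverage (monthly data).
#' @param monthly_noise_sd,temp_noise_sd interannual noise on monthly
#'   ensemble pressures (hPa) and on annual global temperature (degrees C).
#' @param winter_amplification relative amplification of the wintertime
#'   pressure response to warming (annual mean response is unchanged).
#' @param total_ascents,oxygenless_ascents catalog totals.
#' @param month_weights 12 probabilities (summing to 1) of an ascent
#'   falling in each month; default follows the observed oxygenless
#'   pattern (May-dominated, October secondary).
#' @param pressure_bias_percentile mean pressure percentile-of-month that
#'   oxygenless climb days are drawn toward (climbers favour
#'   high-pressure windows).
#' @param bias_concentration beta-distribution concentration of the
#'   percentile draw (larger = tighter around the target percentile).
#' @param temp_cor,wind_cor prescribed correlations of synthetic summit
#'   temperature / wind with the pressure anomaly.
#' @param seed root random seed.
#' @return a validated `synthetic_config` list.
#' @export
synthetic_config <- function(start = "1979-01-01 00:00",
                             end = "2019-12-31 23:00",
                             step_hours = 1,
                             summit_elevation = 8850,
                             seasonal_mean = NULL,
                             seasonal_amplitude = NULL,
                             seasonal_phase_day = NULL,
                             ar1 = 0.98,
                             sigma_winter = 3.5,
                             sigma_summer = 1.2,
                             events_per_winter = 2,
                             event_depth_hPa = 10,
                             event_duration_days = 4,
                             phase_speed_ms = 10,
                             wavelength_km = 6000,
                             station_elevation = 7945,
                             aws_offset_hPa = 0.5,
                             aws_sigma_hPa = 0.2,
                             aws_gap_fraction = 0.1,
                             n_models = 21,
                             sensitivity_mean = 2.2,
                             sensitivity_sd = 0.35,
                             warming_rate_per_decade = 0.25,
                             ens_start_year = 1950,
                             ens_end_year = 2100,
                             monthly_noise_sd = 1.5,
                             temp_noise_sd = 0.1,
                             winter_amplification = 0.25,
                             total_ascents = 10068,
                             oxygenless_ascents = 208,
                             month_weights = NULL,
                             pressure_bias_percentile = 70,
                             bias_concentration = 10,
                             temp_cor = 0.8,
                             wind_cor = -0.1,
                             seed = 1) {
  seas <- fit_seasonal_cycle()
  cfg <- list(
    start = as_utc(start), end = as_utc(end), step_hours = step_hours,
    summit_elevation = summit_elevation,
    seasonal_mean = seasonal_mean %||% seas$mean,
    seasonal_amplitude = seasonal_amplitude %||% seas$amplitude,
    seasonal_phase_day = seasonal_phase_day %||% seas$phase_day,
    ar1 = ar1, sigma_winter = sigma_winter, sigma_summer = sigma_summer,
    events_per_winter = events_per_winter,
    event_depth_hPa = event_depth_hPa,
    event_duration_days = event_duration_days,
    phase_speed_ms = phase_speed_ms, wavelength_km = wavelength_km,
    station_elevation = station_elevation,
    aws_offset_hPa = aws_offset_hPa, aws_sigma_hPa = aws_sigma_hPa,
    aws_gap_fraction = aws_gap_fraction,
    n_models = n_models, sensitivity_mean = sensitivity_mean,
    sensitivity_sd = sensitivity_sd,
    warming_rate_per_decade = warming_rate_per_decade,
    ens_start_year = ens_start_year, ens_end_year = ens_end_year,
    monthly_noise_sd = monthly_noise_sd, temp_noise_sd = temp_noise_sd,
    winter_amplification = winter_amplification,
    total_ascents = total_ascents, oxygenless_ascents = oxygenless_ascents,
    month_weights = month_weights %||%
      (c(0, 0, 0, 4, 170, 2, 0, 3, 5, 23, 0, 1) / 208),
    pressure_bias_percentile = pressure_bias_percentile,
    bias_concentration = bias_concentration,
    temp_cor = temp_cor, wind_cor = wind_cor,
    seed = as.integer(seed)
  )
  validate_synthetic_config(cfg)
  class(cfg) <- "synthetic_config"
  cfg
}

#' @noRd
validate_synthetic_config <- function(cfg) {
  if (is.na(cfg$start) || is.na(cfg$end) || cfg$end <= cfg$start) {
    stopf("invalid period: end must follow start")
  }
  if (cfg$sigma_winter < 0 || cfg$sigma_summer < 0) {
    stopf("noise standard deviations must be non-negative")
  }
  if (cfg$sigma_winter < cfg$sigma_summer) {
    stopf("winter noise must be at least as large as summer noise")
  }
  if (cfg$aws_gap_fraction < 0 || cfg$aws_gap_fraction >= 1) {
    stopf("gap fraction must lie in [0, 1)")
  }
  if (cfg$aws_sigma_hPa < 0 || cfg$monthly_noise_sd < 0 ||
      cfg$temp_noise_sd < 0) {
    stopf("noise standard deviations must be non-negative")
  }
  if (abs(sum(cfg$month_weights) - 1) > 1e-8 || any(cfg$month_weights < 0)) {
    stopf("month weights must be non-negative and sum to 1")
  }
  if (cfg$oxygenless_ascents > cfg$total_ascents) {
    stopf("oxygenless count exceeds total ascents")
  }
  if (cfg$n_models < 2) stopf("need at least 2 ensemble models")
  invisible(cfg)
}

#' @noRd
seasonal_cycle_at <- function(cfg, doy) {
  cfg$seasonal_mean +
    cfg$seasonal_amplitude * cos(2 * pi * (doy - cfg$seasonal_phase_day) / 365.25)
}

#' Generate the synthetic hourly summit pressure series
#'
#' Builds summit "truth" as seasonal sinusoid + AR(1) noise whose
#' stationary standard deviation is interpolated between the mid-winter
#' and mid-summer values + injected negative Gaussian-shaped wave-event
#' anomalies placed in winter (Dec--Feb). The base cycle is raised by the
#' climatological expectation of the event anomalies so the long-run
#' monthly means of the generated series -- events included -- match the
#' configured normals. Bitwise reproducible for a fixed config and seed.
#'
#' @param config a [synthetic_config()].
#' @return list with elements `series` (a `pressure_series` at the summit)
#'   and `truth` (a `truth_record` carrying the seed, the exact event
#'   times and every generating parameter).
#' @export
generate_summit_series <- function(config = synthetic_config()) {
  validate_synthetic_config(config)
  time <- seq(config$start, config$end, by = config$step_hours * 3600)
  doy <- doy365(time)
  # base cycle plus compensation for the climatological event deficit, so
  # the realised monthly means (events included) match the normals
  base <- seasonal_cycle_at(config, doy) - expected_event_anomaly(config, time)

  sig_stat <- config$sigma_summer +
    (config$sigma_winter - config$sigma_summer) * winter_weight(doy)
  noise <- numeric(length(time))
  if (config$sigma_winter > 0) {
    set.seed(substream_seed(config$seed, "summit-noise"))
    innov_sd <- sig_stat * sqrt(1 - config$ar1^2)
    eps <- stats::rnorm(length(time), 0, innov_sd)
    noise <- as.numeric(stats::filter(eps, config$ar1, method = "recursive"))
  }

  ev <- synthetic_event_times(config, time)
  anom <- numeric(length(time))
  if (length(ev)) {
    tau <- config$event_duration_days * 86400 / 2.355  # FWHM -> sd
    tn <- as.numeric(time)
    for (t0 in as.numeric(ev)) {
      w <- abs(tn - t0) < 5 * tau
      anom[w] <- anom[w] -
        config$event_depth_hPa * exp(-0.5 * ((tn[w] - t0) / tau)^2)
    }
  }

  series <- pressure_series(time, base + noise + anom,
                            elevation = config$summit_elevation,
                            source = "synthetic summit truth")
  truth <- structure(
    list(seed = config$seed, config = config,
         event_times = ev,
         seasonal = list(mean = config$seasonal_mean,
                         amplitude = config$seasonal_amplitude,
                         phase_day = config$seasonal_phase_day)),
    class = "truth_record"
  )
  list(series = series, truth = truth)
}

# Deterministic winter event times: exactly events_per_winter draws
# inside each fully covered Dec 10 -- Feb 20 window, redrawn until the
# events of a winter are mutually separated by at least the event
# duration plus 8 days (so detection can tell them apart).
#' @noRd
synthetic_event_times <- function(config, time) {
  if (config$events_per_winter <= 0) return(as_utc(character(0)))
  yrs <- unique(as.POSIXlt(time, tz = "UTC")$year + 1900L)
  set.seed(substream_seed(config$seed, "events"))
  min_sep <- 86400 * (config$event_duration_days + 8)
  out <- c()
  for (y in yrs) {
    w0 <- as_utc(sprintf("%d-12-10 00:00", y))
    w1 <- as_utc(sprintf("%d-02-20 00:00", y + 1))
    if (w0 < min(time) || w1 > max(time)) next
    repeat {
      picks <- sort(stats::runif(config$events_per_winter, as.numeric(w0),
                                 as.numeric(w1)))
      if (config$events_per_winter < 2 || min(diff(picks)) >= min_sep) break
    }
    out <- c(out, picks)
  }
  as.POSIXct(round(sort(out) / 3600) * 3600, origin = "1970-01-01", tz = "UTC")
}

# Climatological expectation of the injected event anomaly at a given
# time, for event centres uniform on the winter window. Added back to
# the base cycle so the long-run monthly means of the generated series
# match the configured normals with events included.
#' @noRd
expected_event_anomaly <- function(config, time) {
  if (config$events_per_winter <= 0 || config$event_depth_hPa == 0) {
    return(numeric(length(time)))
  }
  tau <- config$event_duration_days * 86400 / 2.355
  lt <- as.POSIXlt(time, tz = "UTC")
  yref <- lt$year + 1900L
  yref[lt$mon <= 5] <- yref[lt$mon <= 5] - 1L   # Jan-Jun belong to prior winter
  t_a <- as.numeric(as_utc(sprintf("%d-12-10 00:00", yref)))
  t_b <- t_a + 72 * 86400                       # ~Feb 20
  tn <- as.numeric(time)
  dens <- config$events_per_winter / (t_b - t_a)
  -config$event_depth_hPa * dens * sqrt(2 * pi) * tau *
    (stats::pnorm((t_b - tn) / tau) - stats::pnorm((t_a - tn) / tau))
}

#' Generate pressure-level fields consistent with a summit truth
#'
#' Builds geopotential heights of the requested pressure levels so that
#' log pressure is exactly linear in height through the summit with a
#' smoothly varying (winter-steepened) gradient -- exact log-linear
#' extrapolation therefore recovers the summit truth to floating point,
#' unless `height_noise_m` adds level-height noise. Synthetic
#' summit-interpolated temperature and zonal wind carry prescribed
#' correlations with the pressure anomaly (temperature strongly positive,
#' wind weakly negative, as observed in winter).
#'
#' @param summit_truth a summit `pressure_series` (the generated truth).
#' @param levels pressure levels in hPa; must bracket the summit pressure
#'   at every timestamp.
#' @param config a [synthetic_config()] (correlations, seed).
#' @param height_noise_m iid noise added to every level height, metres.
#' @return a `level_fields` object: `time`, `levels` (descending),
#'   `z` ([time, level] heights, m), `temperature` (K), `wind` (m/s),
#'   plus the wave parameters used by [generate_hovmoller()].
#' @export
generate_level_fields <- function(summit_truth, levels = c(400, 350, 300, 250),
                                  config = synthetic_config(),
                                  height_noise_m = 0) {
  stopifnot(inherits(summit_truth, "pressure_series"))
  levels <- sort(levels, decreasing = TRUE)
  p_s <- summit_truth$pressure
  if (any(p_s >= max(levels) | p_s <= min(levels), na.rm = TRUE)) {
    stopf("summit pressure falls outside the bracketing levels")
  }
  time <- summit_truth$time
  doy <- doy365(time)
  z_s <- attr(summit_truth, "elevation")
  # local gradient of log pressure: steeper in the cold season
  gamma <- 1.4e-4 + 6e-6 * cos(2 * pi * (doy - 15) / 365.25)
  z <- sapply(levels, function(L) z_s + log(p_s / L) / gamma)
  if (height_noise_m > 0) {
    set.seed(substream_seed(config$seed, "level-height-noise"))
    z <- z + matrix(stats::rnorm(length(z), 0, height_noise_m), nrow(z), ncol(z))
  }

  # pressure anomaly standardized within each calendar month (variability
  # is winter-amplified; per-month scaling keeps the prescribed
  # correlation season-invariant)
  anom <- p_s - seasonal_cycle_at(config, doy)
  mo <- as.POSIXlt(time, tz = "UTC")$mon + 1L
  sd_mo <- tapply(anom, mo, stats::sd)
  sd_mo[sd_mo == 0 | is.na(sd_mo)] <- 1
  zscore <- anom / sd_mo[mo]
  set.seed(substream_seed(config$seed, "covariates"))
  mix <- function(rho) {
    rho * zscore + sqrt(1 - rho^2) * stats::rnorm(length(zscore))
  }
  t_clim <- 243 + 8 * cos(2 * pi * (doy - 196) / 365.25)   # K, July max
  u_clim <- 28 + 14 * cos(2 * pi * (doy - 15) / 365.25)    # m/s, winter max
  temperature <- t_clim + 4 * mix(config$temp_cor)
  wind <- pmax(u_clim + 8 * mix(config$wind_cor), 0)

  structure(
    list(time = time, levels = levels, z = z,
         temperature = temperature, wind = wind,
         wave = list(phase_speed_ms = config$phase_speed_ms,
                     wavelength_km = config$wavelength_km,
                     latitude = 28)),
    class = "level_fields"
  )
}

#' @export
print.level_fields <- function(x, ...) {
  cat(sprintf("<level_fields> %d timestamps, levels: %s hPa\n",
              length(x$time), paste(x$levels, collapse = ", ")))
  invisible(x)
}

#' Longitude--time geopotential field of the traveling wave
#'
#' Hovmoller-style matrix of 300-hPa-surface heights on a fixed latitude
#' band: a zonally traveling sinusoidal ridge--trough pattern with the
#' configured phase speed and wavelength. The wave phase depends only on
#' absolute time, so windows cut for different events are mutually
#' consistent.
#'
#' @param fields a `level_fields` (carries the wave parameters), or a
#'   list with a `wave` element.
#' @param start,end window covered (UTC).
#' @param step_hours time step of the matrix.
#' @param amplitude_m wave amplitude in metres.
#' @param dlon longitude grid spacing, degrees.
#' @return a `hovmoller` list: `time`, `lon` (degrees), `x` (metres along
#'   the latitude circle), `z` ([time, lon] heights, m), `latitude`.
#' @export
generate_hovmoller <- function(fields, start, end, step_hours = 6,
                               amplitude_m = 150, dlon = 2.5) {
  wave <- fields$wave
  time <- seq(as_utc(start), as_utc(end), by = step_hours * 3600)
  lon <- seq(0, 360 - dlon, by = dlon)
  lat <- wave$latitude
  circumference <- 2 * pi * 6371e3 * cos(lat * pi / 180)
  x <- lon / 360 * circumference
  # snap to an integer zonal wavenumber so the wave is continuous around
  # the latitude circle (the requested wavelength is approximated)
  k_zonal <- max(1, round(circumference / (wave$wavelength_km * 1000)))
  lambda <- circumference / k_zonal
  tsec <- as.numeric(time)
  phase <- outer(-wave$phase_speed_ms * tsec, x, "+") * (2 * pi / lambda)
  z <- 9100 - amplitude_m * cos(phase)
  structure(list(time = time, lon = lon, x = x, z = z, latitude = lat,
                 wavelength_m = lambda),
            class = "hovmoller")
}

#' Generate a synthetic weather-station series
#'
#' Observed station pressure = summit truth extrapolated down to the
#' station elevation (May-mean log-pressure gradient) + a constant
#' instrument offset + iid noise, with a fraction of timestamps removed in
#' contiguous pseudo-random blocks that emulate station outages. Removed
#' timestamps are kept as explicit `NA`s; exactly
#' `round(gap_fraction * n)` values are blanked.
#'
#' @param truth summit `pressure_series`.
#' @param station_elevation metres.
#' @param offset constant instrument offset, hPa.
#' @param sigma iid observation noise sd, hPa.
#' @param gap_fraction fraction of timestamps lost, in `[0, 1)`.
#' @param seed random seed.
#' @param gradient log-pressure gradient used for the downward
#'   extrapolation, m^-1.
#' @return a `pressure_series` at the station elevation.
#' @export
generate_aws_series <- function(truth, station_elevation = 7945, offset = 0.5,
                                sigma = 0.2, gap_fraction = 0.1, seed = 1,
                                gradient = 1.4e-4) {
  stopifnot(inherits(truth, "pressure_series"))
  if (gap_fraction < 0 || gap_fraction >= 1) stopf("gap fraction must be in [0, 1)")
  if (sigma < 0) stopf("sigma must be non-negative")
  p <- extrapolate_pressure(truth$pressure, attr(truth, "elevation"),
                            station_elevation, gradient) + offset
  n <- length(p)
  set.seed(substream_seed(seed, "aws"))
  if (sigma > 0) p <- p + stats::rnorm(n, 0, sigma)
  n_gap <- round(gap_fraction * n)
  if (n_gap > 0) {
    gone <- logical(n)
    while (sum(gone) < n_gap) {
      len <- min(sample(6:72, 1), n_gap - sum(gone))
      st <- sample.int(n - len + 1, 1)
      span <- st:(st + len - 1)
      span <- span[!gone[span]][seq_len(min(len, n_gap - sum(gone)))]
      gone[span] <- TRUE
    }
    p[gone] <- NA_real_
  }
  pressure_series(truth$time, p, elevation = station_elevation,
                  source = sprintf("synthetic AWS (offset %+0.2f hPa)", offset))
}

#' Generate a synthetic climate-model ensemble
#'
#' Monthly summit-pressure series for `n_models` models plus an annual
#' global-mean temperature series per model. Each model's pressure is, by
#' construction, the monthly climatology plus its prescribed true
#' sensitivity (hPa per degree of global warming) times the forced
#' temperature path, with winter-amplified monthly response factors (mean
#' 1 across the year) and additive interannual noise -- so 30-year-mean
#' regression recovers the injected annual-mean sensitivity.
#'
#' @param config a [synthetic_config()].
#' @return a `cmip_ensemble`: `years`, `pressure` array
#'   `[model, year, month]` (hPa), `tas` matrix `[model, year]` (deg C
#'   anomaly), `month_factor`, and a `truth_record` with the drawn
#'   sensitivities.
#' @export
generate_cmip_ensemble <- function(config = synthetic_config()) {
  validate_synthetic_config(config)
  years <- config$ens_start_year:config$ens_end_year
  ny <- length(years)
  if (ny < 31) stopf("need at least 31 years for 30-year running means")
  nm <- config$n_models

  set.seed(substream_seed(config$seed, "ensemble"))
  sens <- stats::rnorm(nm, config$sensitivity_mean, config$sensitivity_sd)
  path <- config$warming_rate_per_decade * (years - years[1]) / 10

  dim_days <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
  mid <- cumsum(dim_days) - dim_days / 2
  mf <- 1 + config$winter_amplification * cos(2 * pi * (mid - 15) / 365.25)
  mf <- mf / mean(mf)
  clim <- seasonal_cycle_at(config, mid)

  tas <- matrix(0, nm, ny)
  pres <- array(0, c(nm, ny, 12))
  for (m in seq_len(nm)) {
    tas[m, ] <- path + stats::rnorm(ny, 0, config$temp_noise_sd)
    forced <- sens[m] * outer(path, mf)           # [year, month]
    noise <- matrix(stats::rnorm(ny * 12, 0, config$monthly_noise_sd), ny, 12)
    pres[m, , ] <- rep(clim, each = ny) + forced + noise
  }
  truth <- structure(list(seed = config$seed, sensitivities = sens,
                          warming_path = path, month_factor = mf),
                     class = "truth_record")
  structure(list(years = years, pressure = pres, tas = tas,
                 month_factor = mf, truth = truth),
            class = "cmip_ensemble")
}

#' @export
print.cmip_ensemble <- function(x, ...) {
  cat(sprintf("<cmip_ensemble> %d models x %d years (monthly)\n",
              dim(x$pressure)[1], dim(x$pressure)[2]))
  invisible(x)
}

#' Generate a synthetic ascent catalog
#'
#' Distributes `total_ascents` summit days over the covered years with the
#' configured month weights; `oxygenless_ascents` of them are flagged
#' oxygenless. Climb days are drawn with a high-pressure selection bias:
#' the target pressure percentile-of-month is beta-distributed around
#' `pressure_bias_percentile` for oxygenless climbs (and a milder 60th
#' percentile for assisted climbs), and the day of the chosen month-year
#' whose daily-mean pressure sits nearest that percentile is selected.
#'
#' @param config a [synthetic_config()].
#' @param summit_series summit `pressure_series` covering the catalog
#'   period.
#' @return an `ascent_catalog` data.frame: `date`, `n_climbers`,
#'   `oxygenless`.
#' @export
generate_ascent_catalog <- function(config = synthetic_config(), summit_series) {
  validate_synthetic_config(config)
  stopifnot(inherits(summit_series, "pressure_series"))
  daily <- daily_means(summit_series)
  daily$year <- as.integer(format(daily$date, "%Y"))
  daily$month <- as.integer(format(daily$date, "%m"))
  years <- unique(daily$year)

  set.seed(substream_seed(config$seed, "ascents"))
  draw_days <- function(n, target_pct) {
    months <- sample.int(12, n, replace = TRUE, prob = config$month_weights)
    kappa <- config$bias_concentration
    pct <- stats::rbeta(n, target_pct / 100 * kappa,
                        (1 - target_pct / 100) * kappa)
    dates <- as.Date(rep(NA_integer_, n), origin = "1970-01-01")
    yr <- sample(years, n, replace = TRUE)
    for (i in seq_len(n)) {
      pool <- daily[daily$year == yr[i] & daily$month == months[i] &
                      !is.na(daily$pressure), ]
      if (!nrow(pool)) {
        pool <- daily[daily$month == months[i] & !is.na(daily$pressure), ]
      }
      rk <- rank(pool$pressure) / (nrow(pool) + 1)
      dates[i] <- pool$date[which.min(abs(rk - pct[i]))]
    }
    dates
  }

  n_ox <- config$oxygenless_ascents
  n_as <- config$total_ascents - n_ox
  d_ox <- draw_days(n_ox, config$pressure_bias_percentile)
  d_as <- draw_days(n_as, 60)
  flat <- data.frame(
    date = c(d_ox, d_as),
    oxygenless = rep(c(TRUE, FALSE), c(n_ox, n_as))
  )
  agg <- stats::aggregate(list(n_climbers = rep(1L, nrow(flat))),
                          by = flat[c("date", "oxygenless")], FUN = sum)
  agg <- agg[order(agg$date, agg$oxygenless), c("date", "n_climbers", "oxygenless")]
  rownames(agg) <- NULL
  class(agg) <- c("ascent_catalog", "data.frame")
  agg
}

#' Write a truth record to YAML
#'
#' Serialises the exact generating parameters (including the seed that
#' reproduces the dataset bit-for-bit) alongside the outputs.
#'
#' @param truth a `truth_record`.
#' @param path output file.
#' @export
write_truth_yaml <- function(truth, path) {
  stopifnot(inherits(truth, "truth_record"))
  ser <- rapply(unclass(truth), function(x) {
    if (inherits(x, "POSIXct")) format(x, "%Y-%m-%dT%H:%M:%SZ") else x
  }, how = "replace")
  yaml::write_yaml(ser, path)
  invisible(path)
}
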