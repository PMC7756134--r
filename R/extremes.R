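#' Find the n lowest-pressure events in a series
#'
#' Greedy selection of the globally lowest pressures with an exclusion
#' window around each accepted event, so the events are separated local
#' minima rather than neighbouring hours of one deep trough. Deterministic
#' and invariant to how the input was chunked.
#'
#' @param series a `pressure_series`.
#' @param n number of events requested.
#' @param min_separation_days minimum time separation between events.
#' @return an `event_set` data.frame in selection order (ascending event
#'   pressure): `time`, `pressure`, `month`; attributes `min_separation_days`,
#'   `n_requested`. A warning is raised if fewer than `n` separable minima
#'   exist.
#' @export
find_lowest_events <- function(series, n = 20, min_separation_days = 10) {
  stopifnot(inherits(series, "pressure_series"))
  ok <- which(!is.na(series$pressure))
  ord <- ok[order(series$pressure[ok])]
  sep <- min_separation_days * 86400
  tn <- as.numeric(series$time)
  picked <- integer(0)
  for (i in ord) {
    if (length(picked) == n) break
    if (!length(picked) || min(abs(tn[i] - tn[picked])) >= sep) {
      picked <- c(picked, i)
    }
  }
  if (length(picked) < n) {
    warning(sprintf("only %d separable events found (requested %d)",
                    length(picked), n), call. = FALSE)
  }
  out <- data.frame(
    time = series$time[picked],
    pressure = series$pressure[picked],
    month = as.POSIXlt(series$time[picked], tz = "UTC")$mon + 1L
  )
  attr(out, "min_separation_days") <- min_separation_days
  attr(out, "n_requested") <- n
  class(out) <- c("event_set", "data.frame")
  out
}

#' Composite pressure anomalies around events
#'
#' Anomalies are the series minus the smoothed day-of-year climatology
#' mean; for each event with full coverage of the +/- window the anomaly
#' is sampled on an hourly lag axis centred on the event, then averaged
#' across events. Events without full window coverage are excluded with a
#' warning.
#'
#' @param series a `pressure_series` (hourly).
#' @param events an `event_set`.
#' @param window_days half-width of the lag window, days.
#' @param climatology a [doy_climatology()] of the same series.
#' @return a `composite_result`: `lag_hours`, `mean`, `sd`, per-event
#'   `matrix` (events x lags), `n_events`.
#' @export
composite_anomalies <- function(series, events, window_days = 10,
                                climatology = doy_climatology(series)) {
  stopifnot(inherits(series, "pressure_series"))
  anom <- series$pressure - climatology_at(climatology, series$time)
  step <- as.numeric(difftime(series$time[2], series$time[1], units = "hours"))
  lag_hours <- seq(-window_days * 24, window_days * 24, by = step)
  half <- window_days * 24 / step
  tn <- as.numeric(series$time)

  rows <- list()
  for (k in seq_len(nrow(events))) {
    i0 <- match(as.numeric(events$time[k]), tn)
    if (is.na(i0) || i0 - half < 1 || i0 + half > length(anom)) {
      warning(sprintf("event %s lacks full +/-%d day coverage; excluded",
                      format(events$time[k]), window_days), call. = FALSE)
      next
    }
    seg <- anom[(i0 - half):(i0 + half)]
    if (anyNA(seg)) {
      warning(sprintf("event %s window contains missing values; excluded",
                      format(events$time[k])), call. = FALSE)
      next
    }
    rows[[length(rows) + 1]] <- seg
  }
  if (!length(rows)) stopf("no usable events for compositing")
  m <- do.call(rbind, rows)
  sd_lag <- if (nrow(m) > 1) apply(m, 2, stats::sd) else rep(0, ncol(m))
  structure(
    list(lag_hours = lag_hours,
         mean = colMeans(m),
         sd = sd_lag,
         matrix = m, n_events = nrow(m)),
    class = "composite_result"
  )
}

#' @export
print.composite_result <- function(x, ...) {
  i <- which.min(x$mean)
  cat(sprintf("<composite> %d events; minimum %.1f hPa at lag %+d h\n",
              x$n_events, x$mean[i], x$lag_hours[i]))
  invisible(x)
}

#' Estimate zonal phase speed and transit time of the wave behind an event
#'
#' Tracks the zonal displacement of the ridge--trough pattern through the
#' event window by following the phase of the dominant zonal harmonic of
#' successive longitude profiles. The harmonic is picked from the
#' time-averaged Fourier amplitude spectrum (a traveling wave cancels in
#' the time-mean profile, so spectra are averaged, not profiles); the
#' phase increment per step, unwrapped to within half a wavelength, gives
#' the displacement, and the phase speed is the median displacement rate.
#' Ridge-to-trough distance is half the dominant wavelength and the
#' transit time is distance over speed. Events whose phase increments are
#' not mutually consistent (incoherent pattern), or whose pattern does
#' not move, are flagged and should be excluded from summary medians.
#'
#' @param hov a [generate_hovmoller()] field covering the event window
#'   (or any longitude--time matrix object of the same shape).
#' @param step_pairs time separation, in time steps of `hov`, between the
#'   profile pairs whose phases are differenced.
#' @param min_coherence minimum circular concentration (mean resultant
#'   length) of the per-step phase increments for the event to count as
#'   coherent.
#' @return a `wave_estimate` row: `phase_speed_ms` (positive eastward),
#'   `wavelength_m`, `ridge_trough_m`, `transit_days`, `coherence`,
#'   `coherent` (logical), `propagating` (logical).
#' @export
estimate_phase_speed <- function(hov, step_pairs = 1, min_coherence = 0.9) {
  z <- hov$z
  nt <- nrow(z)
  nx <- ncol(z)
  if (nt <= step_pairs) stopf("window too short for phase-speed tracking")
  dx <- hov$x[2] - hov$x[1]
  dt <- as.numeric(difftime(hov$time[2], hov$time[1], units = "secs")) * step_pairs

  # dominant zonal harmonic from the time-averaged amplitude spectrum
  kmax <- floor(nx / 2) - 1
  ft <- t(apply(z, 1, function(r) stats::fft(r - mean(r))[2:(kmax + 1)]))
  spec <- colMeans(Mod(ft))
  k_dom <- which.max(spec)
  wavelength <- (nx * dx) / k_dom

  # phase of the dominant harmonic per time step; a pattern moving east
  # by d drops the phase by 2*pi*d/wavelength
  phase <- Arg(ft[, k_dom])
  dphi <- phase[seq_len(nt - step_pairs) + step_pairs] -
    phase[seq_len(nt - step_pairs)]
  dphi <- ((dphi + pi) %% (2 * pi)) - pi   # unwrap to (-pi, pi]
  speeds <- -dphi / (2 * pi) * wavelength / dt

  coherence <- Mod(mean(exp(1i * dphi)))
  coherent <- coherence >= min_coherence
  speed <- stats::median(speeds)
  propagating <- coherent && abs(speed) > 0.5
  transit <- if (propagating) (wavelength / 2) / abs(speed) / 86400 else NA_real_
  structure(
    data.frame(phase_speed_ms = speed, wavelength_m = wavelength,
               ridge_trough_m = wavelength / 2, transit_days = transit,
               coherence = coherence, coherent = coherent,
               propagating = propagating),
    class = c("wave_estimate", "data.frame")
  )
}

#' Per-event wave estimates and their summary
#'
#' Runs [estimate_phase_speed()] on a window around every event and
#' summarises the transit times (median and quartiles) over the coherent,
#' propagating events.
#'
#' @param fields a `level_fields` (wave parameters for the synthetic
#'   Hovmoller field).
#' @param events an `event_set`.
#' @param window_days half-width of each event window.
#' @param ... passed to [estimate_phase_speed()].
#' @return list with `per_event` (data.frame) and `summary`
#'   (median/quartiles of transit days and speed).
#' @export
wave_transit_summary <- function(fields, events, window_days = 3, ...) {
  per <- do.call(rbind, lapply(seq_len(nrow(events)), function(k) {
    hov <- generate_hovmoller(fields,
                              events$time[k] - window_days * 86400,
                              events$time[k] + window_days * 86400)
    estimate_phase_speed(hov, ...)
  }))
  per$event_time <- events$time
  use <- per$coherent & per$propagating
  if (!any(use)) stopf("no coherent propagating events")
  q <- stats::quantile(per$transit_days[use], c(0.25, 0.5, 0.75))
  list(per_event = per,
       summary = list(transit_days_median = unname(q[2]),
                      transit_days_q25 = unname(q[1]),
                      transit_days_q75 = unname(q[3]),
                      phase_speed_median = stats::median(per$phase_speed_ms[use]),
                      n_used = sum(use)))
}

#' Pearson correlation between summit pressure and a covariate
#'
#' Month-filtered, pairwise-complete Pearson correlation (e.g. winter
#' pressure against summit-level temperature or wind).
#'
#' @param series a `pressure_series`.
#' @param covariate numeric vector aligned with `series$time`.
#' @param months calendar months to include (default winter, Dec--Feb).
#' @return correlation coefficient; `NA` with a warning if either side
#'   has zero variance.
#' @export
pressure_covariate_correlation <- function(series, covariate,
                                           months = c(12, 1, 2)) {
  stopifnot(inherits(series, "pressure_series"),
            length(covariate) == nrow(series))
  mo <- as.POSIXlt(series$time, tz = "UTC")$mon + 1L
  keep <- mo %in% months & !is.na(series$pressure) & !is.na(covariate)
  if (sum(keep) < 3) stopf("fewer than 3 paired samples in selected months")
  x <- series$pressure[keep]
  y <- covariate[keep]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance; correlation undefined", call. = FALSE)
    return(NA_real_)
  }
  stats::cor(x, y)
}
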