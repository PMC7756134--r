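#' Theil-Sen trend estimate with percentile bounds
#'
#' Median of all pairwise slopes between distinct years; the uncertainty
#' band is the 5th--95th percentile of the pairwise-slope distribution
#' (an optional bootstrap variant resamples years instead). Slopes are
#' reported per decade.
#'
#' @param years numeric years.
#' @param values annual statistic (e.g. annual mean pressure), hPa.
#' @param probs lower/upper percentile bounds of the slope distribution.
#' @param ci method for the bounds: `"pairwise"` (percentiles of the raw
#'   pairwise slopes) or `"bootstrap"` (percentiles of Theil-Sen medians
#'   over resampled years).
#' @param n_boot bootstrap replicates when `ci = "bootstrap"`.
#' @param statistic label carried in the result.
#' @return a `trend_result` list: `slope`, `lower`, `upper` (hPa per
#'   decade), `n`, `statistic`.
#' @export
theil_sen <- function(years, values, probs = c(0.05, 0.95),
                      ci = c("pairwise", "bootstrap"), n_boot = 500,
                      statistic = "annual") {
  ci <- match.arg(ci)
  keep <- !is.na(years) & !is.na(values)
  years <- years[keep]; values <- values[keep]
  if (length(years) < 3) stopf("need at least 3 points")
  slopes <- pairwise_slopes(years, values)
  if (!length(slopes)) stopf("all years duplicated; no valid pairs")
  med <- stats::median(slopes)
  if (ci == "pairwise") {
    bounds <- stats::quantile(slopes, probs, names = FALSE)
  } else {
    meds <- vapply(seq_len(n_boot), function(b) {
      i <- sample(length(years), replace = TRUE)
      s <- pairwise_slopes(years[i], values[i])
      if (length(s)) stats::median(s) else NA_real_
    }, numeric(1))
    bounds <- stats::quantile(meds, probs, na.rm = TRUE, names = FALSE)
  }
  structure(list(slope = 10 * med, lower = 10 * bounds[1],
                 upper = 10 * bounds[2], n = length(years),
                 statistic = statistic, ci = ci),
            class = "trend_result")
}

#' @noRd
pairwise_slopes <- function(x, y) {
  n <- length(x)
  i <- rep(seq_len(n - 1), times = (n - 1):1)
  j <- unlist(lapply(2:n, function(k) k:n))
  dx <- x[j] - x[i]
  ok <- dx != 0
  (y[j] - y[i])[ok] / dx[ok]
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf("<trend> %s: %.2f (%.2f to %.2f) hPa/decade over %d years\n",
              x$statistic, x$slope, x$lower, x$upper, x$n))
  invisible(x)
}

#' Convert a pressure trend to a temperature sensitivity
#'
#' Elementwise ratio of a pressure trend (and its bounds) to the
#' concurrent global-mean temperature trend, giving hPa per degree C.
#'
#' @param pressure_trend a `trend_result` or numeric slope, hPa/decade.
#' @param temperature_trend global-mean warming rate, deg C/decade
#'   (non-zero).
#' @return a `sensitivity_result` with `median`, `lower`, `upper`
#'   (hPa per deg C).
#' @export
trend_to_sensitivity <- function(pressure_trend, temperature_trend) {
  if (temperature_trend == 0) stopf("temperature trend must be non-zero")
  if (inherits(pressure_trend, "trend_result")) {
    out <- list(median = pressure_trend$slope / temperature_trend,
                lower = pressure_trend$lower / temperature_trend,
                upper = pressure_trend$upper / temperature_trend,
                statistic = pressure_trend$statistic,
                per_model = NULL)
  } else {
    out <- list(median = pressure_trend / temperature_trend,
                lower = NA_real_, upper = NA_real_,
                statistic = "scalar", per_model = NULL)
  }
  class(out) <- "sensitivity_result"
  out
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat(sprintf("<sensitivity> %s: %.2f (%.2f to %.2f) hPa/degC%s\n",
              x$statistic, x$median, x$lower, x$upper,
              if (!is.null(x$per_model))
                sprintf(" across %d models", length(x$per_model)) else ""))
  invisible(x)
}

#' Ensemble sensitivity of summit pressure to global warming
#'
#' Per model: compute the annual statistic (mean, min or max of the twelve
#' monthly values per calendar year, or a single month's series), apply a
#' centred 30-year running mean to both the statistic and the annual
#' global-mean temperature to filter interannual variability, and regress
#' the smoothed statistic on the smoothed temperature (ordinary least
#' squares). The ensemble summary is the median and 5th--95th percentile
#' range of the per-model slopes. Models with a degenerate (constant)
#' smoothed temperature are excluded with a warning; if every model is
#' degenerate the regressor is flagged as unusable.
#'
#' @param ensemble a `cmip_ensemble` (see [generate_cmip_ensemble()]).
#' @param statistic `"mean"`, `"min"` or `"max"` of the monthly values
#'   within each year.
#' @param month optional single month (1--12); overrides `statistic` and
#'   uses that month's series directly.
#' @param window running-mean window, years.
#' @return a `sensitivity_result` with per-model slopes.
#' @export
cmip_sensitivity <- function(ensemble, statistic = c("mean", "min", "max"),
                             month = NULL, window = 30) {
  stopifnot(inherits(ensemble, "cmip_ensemble"))
  statistic <- match.arg(statistic)
  ny <- dim(ensemble$pressure)[2]
  if (ny < window + 1) stopf("need more than %d years of data", window)
  nm <- dim(ensemble$pressure)[1]
  run <- function(x) {
    out <- stats::filter(x, rep(1 / window, window), sides = 2)
    as.numeric(out)
  }
  slopes <- rep(NA_real_, nm)
  for (m in seq_len(nm)) {
    stat <- if (!is.null(month)) {
      ensemble$pressure[m, , month]
    } else {
      apply(ensemble$pressure[m, , ], 1, statistic)
    }
    ps <- run(stat)
    ts <- run(ensemble$tas[m, ])
    keep <- !is.na(ps) & !is.na(ts)
    if (stats::sd(ts[keep]) < 1e-12) {
      warning(sprintf("model %d: constant smoothed temperature; excluded", m),
              call. = FALSE)
      next
    }
    slopes[m] <- stats::cov(ps[keep], ts[keep]) / stats::var(ts[keep])
  }
  ok <- !is.na(slopes)
  if (!any(ok)) stopf("degenerate regressor: smoothed temperature constant in every model")
  q <- stats::quantile(slopes[ok], c(0.05, 0.5, 0.95), names = FALSE)
  structure(list(median = q[2], lower = q[1], upper = q[3],
                 statistic = if (!is.null(month)) sprintf("month %d", month)
                             else sprintf("annual %s", statistic),
                 per_model = slopes),
            class = "sensitivity_result")
}

#' Project a summit-pressure statistic under warming
#'
#' Linear projection `baseline + sensitivity * delta_T`, with the implied
#' change in VO2max (percent, via the calibrated physiology model) and in
#' apparent elevation (via the May-mean log-pressure gradient: a pressure
#' rise lowers the elevation at which the baseline pressure would be
#' met). Warming beyond +/-4.5 degrees C from the baseline climate is an
#' extrapolation beyond the scenario range and is flagged.
#'
#' @param baseline baseline statistic, hPa.
#' @param sensitivity hPa per deg C (scalar or `sensitivity_result`).
#' @param delta_T warming relative to the baseline climate, deg C.
#' @param vo2_model optional [calibrate_vo2_model()] for the VO2 column.
#' @return a `projection_result` data.frame.
#' @export
project_stat <- function(baseline, sensitivity, delta_T, vo2_model = NULL) {
  s <- if (inherits(sensitivity, "sensitivity_result")) sensitivity$median else sensitivity
  proj <- baseline + s * delta_T
  k <- physio_constants()
  dz <- log(proj / baseline) / k$gamma_may
  dvo2 <- rep(NA_real_, length(proj))
  if (!is.null(vo2_model)) {
    in_range <- proj >= vo2_model$range[1] & baseline >= vo2_model$range[1]
    dvo2[in_range] <- 100 * (vo2max(proj[in_range], vo2_model) /
                               vo2max(baseline, vo2_model) - 1)
  }
  out <- data.frame(baseline_hPa = baseline, delta_T = delta_T,
                    projected_hPa = proj,
                    apparent_elevation_change_m = dz,
                    vo2_change_pct = dvo2,
                    extrapolated = abs(delta_T) > 4.5)
  class(out) <- c("projection_result", "data.frame")
  out
}

#' Warming needed to move a statistic to a target value
#'
#' `(target - current) / sensitivity`; a negative answer is the amount of
#' cooling that would bring the statistic down to the target.
#'
#' @param current,target statistic values, hPa.
#' @param sensitivity hPa per deg C (> 0).
#' @return required warming, deg C.
#' @export
warming_to_threshold <- function(current, target, sensitivity) {
  s <- if (inherits(sensitivity, "sensitivity_result")) sensitivity$median else sensitivity
  if (any(s <= 0)) stopf("sensitivity must be positive")
  (target - current) / s
}

#' Shift of the monthly pressure distribution between two decades
#'
#' Per-month quantiles (5, 25, 50, 75, 95 percent) of hourly pressure for
#' each of two decades, and their differences (last minus first). Both
#' decades must be fully covered by the series.
#'
#' @param series a `pressure_series`.
#' @param first_decade,last_decade integer year ranges `c(start, end)`.
#' @param probs quantiles to compare.
#' @return data.frame with one row per month x quantile: `month`, `prob`,
#'   `first`, `last`, `difference`.
#' @export
decadal_distribution_shift <- function(series,
                                       first_decade = c(1979, 1988),
                                       last_decade = c(2010, 2019),
                                       probs = c(0.05, 0.25, 0.5, 0.75, 0.95)) {
  stopifnot(inherits(series, "pressure_series"))
  lt <- as.POSIXlt(series$time, tz = "UTC")
  yr <- lt$year + 1900L
  mo <- lt$mon + 1L
  for (dec in list(first_decade, last_decade)) {
    have <- unique(yr[yr >= dec[1] & yr <= dec[2] & !is.na(series$pressure)])
    if (!setequal(have, dec[1]:dec[2])) {
      stopf("decade %d-%d not fully covered by the series", dec[1], dec[2])
    }
  }
  qtab <- function(dec) {
    sel <- yr >= dec[1] & yr <= dec[2] & !is.na(series$pressure)
    do.call(rbind, lapply(1:12, function(m) {
      q <- stats::quantile(series$pressure[sel & mo == m], probs, names = FALSE)
      data.frame(month = m, prob = probs, q = q)
    }))
  }
  a <- qtab(first_decade)
  b <- qtab(last_decade)
  data.frame(month = a$month, prob = a$prob, first = a$q, last = b$q,
             difference = b$q - a$q)
}
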