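#' Vertical gradient of log pressure between two levels
#'
#' The hypsometric relationship makes log pressure close to linear in
#' geometric height over a layer, with slope (the "gradient") inversely
#' proportional to the layer's mean virtual temperature. The gradient is
#' estimated locally from the two pressure levels bracketing the target
#' elevation.
#'
#' @param p_lower,p_upper pressures (hPa) at the lower and upper level;
#'   `p_lower >= p_upper > 0`.
#' @param z_lower,z_upper geopotential heights (m), `z_upper > z_lower`.
#' @return gradient in m^-1 (positive; 0 with a `degenerate` attribute if
#'   the two pressures are equal).
#' @export
log_pressure_gradient <- function(p_lower, z_lower, p_upper, z_upper) {
  if (any(z_upper <= z_lower)) stopf("z_upper must exceed z_lower")
  if (any(p_upper <= 0) || any(p_lower < p_upper)) {
    stopf("need p_lower >= p_upper > 0")
  }
  g <- (log(p_lower) - log(p_upper)) / (z_upper - z_lower)
  attr(g, "degenerate") <- p_lower == p_upper
  g
}

#' Extrapolate pressure along a log-linear profile
#'
#' `p_ref * exp(-gradient * (z_target - z_ref))`: exact inverse of
#' [log_pressure_gradient()] on a log-linear layer, strictly decreasing in
#' the target elevation.
#'
#' @param p_ref pressure (hPa) at reference height `z_ref` (m).
#' @param z_target target height (m).
#' @param gradient vertical gradient of log pressure (m^-1, > 0).
#' @export
extrapolate_pressure <- function(p_ref, z_ref, z_target, gradient) {
  if (any(gradient <= 0)) stopf("gradient must be positive")
  p_ref * exp(-gradient * (z_target - z_ref))
}

#' Constant bias adjustment from an observation overlap
#'
#' Mean of (observed - modelled) pressure over the overlapping,
#' pairwise-complete hours; adding the returned offset to the model series
#' zeroes its mean bias against the station.
#'
#' @param model,obs `pressure_series` objects on a shared time base.
#' @param min_hours minimum overlap required (default one day).
#' @param by_month if `TRUE`, returns a 12-vector of per-calendar-month
#'   offsets instead of a single constant.
#' @return offset in hPa (add to the model series).
#' @export
bias_adjustment <- function(model, obs, min_hours = 24, by_month = FALSE) {
  ov <- overlap_pairs(obs, model)
  if (nrow(ov) == 0) stopf("no overlapping observations")
  if (nrow(ov) < min_hours) {
    stopf("only %d overlapping hours (need >= %d)", nrow(ov), min_hours)
  }
  if (by_month) {
    mo <- as.POSIXlt(ov$time, tz = "UTC")$mon + 1L
    off <- rep(NA_real_, 12)
    agg <- tapply(ov$a - ov$b, mo, mean)
    off[as.integer(names(agg))] <- as.numeric(agg)
    return(off)
  }
  mean(ov$a - ov$b)
}

# Per-timestamp bracketing pair around a target height, vectorised over
# rows of a [time, level] height matrix with heights ascending along the
# row (levels in descending pressure). Returns the index of the lower
# member of the pair, or NA when the target sits above the top level by
# more than one full level spacing. Targets below the lowest level height
# use the lowest adjacent pair (minimal extrapolation distance).
#' @noRd
bracket_index <- function(z, z_target) {
  n <- ncol(z)
  cnt <- rowSums(z < z_target)
  j <- pmin(pmax(cnt, 1L), n - 1L)
  too_high <- cnt == n & (z_target - z[, n]) > (z[, n] - z[, n - 1])
  j[too_high] <- NA_integer_
  j
}

#' Reconstruct a summit pressure series from pressure-level fields
#'
#' For every timestamp, the two pressure levels whose geopotential heights
#' straddle the summit elevation are selected, the local gradient of log
#' pressure is computed from that pair, and pressure is extrapolated from
#' the lower member of the pair to the summit; a constant (or
#' per-calendar-month) bias adjustment is then added. When the summit sits
#' below the lowest level's height the lowest adjacent pair is used; when
#' it sits above the topmost height by more than one level spacing the
#' timestamp is flagged missing rather than extrapolated blindly.
#'
#' @param fields a `level_fields` object (see [generate_level_fields()]).
#' @param summit_elevation target elevation in metres.
#' @param adjustment additive bias adjustment in hPa: a scalar, or a
#'   12-vector of per-month offsets.
#' @return a `pressure_series` at `summit_elevation`.
#' @export
reconstruct_summit_series <- function(fields, summit_elevation = 8850,
                                      adjustment = 0) {
  stopifnot(inherits(fields, "level_fields"))
  lev <- fields$levels          # descending pressure
  z <- fields$z                 # [time, level], heights ascending with column
  n <- length(fields$time)
  j <- bracket_index(z, summit_elevation)
  p <- rep(NA_real_, n)
  ok <- which(!is.na(j))
  if (length(ok)) {
    jo <- j[ok]
    z_lo <- z[cbind(ok, jo)]
    z_up <- z[cbind(ok, jo + 1L)]
    g <- (log(lev[jo]) - log(lev[jo + 1L])) / (z_up - z_lo)
    p[ok] <- lev[jo] * exp(-g * (summit_elevation - z_lo))
  }
  if (length(adjustment) == 12) {
    mo <- as.POSIXlt(fields$time, tz = "UTC")$mon + 1L
    p <- p + adjustment[mo]
  } else {
    p <- p + adjustment
  }
  pressure_series(fields$time, p, elevation = summit_elevation,
                  source = "gradient reconstruction")
}

#' Direct linear-in-height interpolation of pressure (comparison method)
#'
#' Interpolates pressure linearly in geopotential height between the
#' bracketing levels. Ignoring the exponential profile biases the estimate
#' low within a layer; provided as the baseline the gradient method is
#' judged against.
#'
#' @inheritParams reconstruct_summit_series
#' @export
interpolate_direct_series <- function(fields, summit_elevation = 8850) {
  stopifnot(inherits(fields, "level_fields"))
  lev <- fields$levels
  z <- fields$z
  n <- length(fields$time)
  j <- bracket_index(z, summit_elevation)
  p <- rep(NA_real_, n)
  ok <- which(!is.na(j))
  if (length(ok)) {
    jo <- j[ok]
    z_lo <- z[cbind(ok, jo)]
    z_up <- z[cbind(ok, jo + 1L)]
    w <- (summit_elevation - z_lo) / (z_up - z_lo)
    p[ok] <- (1 - w) * lev[jo] + w * lev[jo + 1L]
  }
  pressure_series(fields$time, p, elevation = summit_elevation,
                  source = "direct interpolation")
}

#' Validate an estimated series against observations
#'
#' Mean absolute error, Pearson correlation and mean bias over the
#' pairwise-complete overlap; missing timestamps are excluded pairwise,
#' never interpolated.
#'
#' @param estimate,obs `pressure_series` objects.
#' @return a `validation_report` list: `mae`, `r`, `bias`, `n`,
#'   `r_defined`.
#' @export
validate_reconstruction <- function(estimate, obs) {
  ov <- overlap_pairs(estimate, obs)
  if (nrow(ov) < 2) stopf("need at least 2 overlapping points")
  err <- ov$a - ov$b
  r_def <- stats::sd(ov$a) > 0 && stats::sd(ov$b) > 0
  structure(
    list(mae = mean(abs(err)), bias = mean(err),
         r = if (r_def) stats::cor(ov$a, ov$b) else NA_real_,
         r_defined = r_def, n = nrow(ov)),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation> n = %d overlapping hours\n", x$n))
  cat(sprintf("  MAE %.3f hPa | bias %+.3f hPa | r %s\n",
              x$mae, x$bias,
              if (x$r_defined) sprintf("%.4f", x$r) else "undefined (zero variance)"))
  invisible(x)
}

#' Smoothed day-of-year climatology
#'
#' Per-day mean, minimum and maximum across all years, each smoothed with
#' a circular Gaussian kernel so the curve is continuous across the
#' new-year boundary. Feb 29 is folded into day 59, giving a fixed 365-day
#' axis. Requires at least two full years of coverage.
#'
#' @param series a `pressure_series`.
#' @param sigma_days Gaussian kernel standard deviation in days
#'   (`0` disables smoothing).
#' @return a `doy_climatology`: data.frame `doy`, `mean`, `min`, `max`
#'   with the kernel width as attribute `sigma_days`.
#' @export
doy_climatology <- function(series, sigma_days = 7) {
  stopifnot(inherits(series, "pressure_series"))
  ok <- !is.na(series$pressure)
  span_days <- as.numeric(difftime(max(series$time[ok]), min(series$time[ok]),
                                   units = "days"))
  if (span_days < 2 * 365 - 1) stopf("need at least 2 full years of data")
  doy <- doy365(series$time[ok])
  p <- series$pressure[ok]
  if (length(unique(doy)) < 365) stopf("series does not cover every day of year")
  mu <- tapply(p, doy, mean)
  lo <- tapply(p, doy, min)
  hi <- tapply(p, doy, max)
  ord <- order(as.integer(names(mu)))
  curve <- data.frame(
    doy = as.integer(names(mu))[ord],
    mean = smooth_circular(as.numeric(mu)[ord], sigma_days, 365),
    min = smooth_circular(as.numeric(lo)[ord], sigma_days, 365),
    max = smooth_circular(as.numeric(hi)[ord], sigma_days, 365)
  )
  attr(curve, "sigma_days") <- sigma_days
  class(curve) <- c("doy_climatology", "data.frame")
  curve
}

# Climatology mean evaluated at arbitrary timestamps.
#' @noRd
climatology_at <- function(clim, time) clim$mean[doy365(time)]
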