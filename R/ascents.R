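# Daily mean pressures with day boundaries in Nepal local time
# (UTC+5:45), since summit days are what the catalog records.
#' @noRd
daily_means <- function(series, tz_offset_hours = 5.75) {
  local <- series$time + tz_offset_hours * 3600
  date <- as.Date(format(local, "%Y-%m-%d"))
  agg <- tapply(series$pressure, date, function(x) {
    if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  })
  data.frame(date = as.Date(names(agg)), pressure = as.numeric(agg))
}

#' Read / write an ascent catalog as CSV
#'
#' Columns `date,n_climbers,oxygenless` (ISO dates; oxygenless as
#' TRUE/FALSE).
#'
#' @param x an `ascent_catalog`.
#' @param path file path.
#' @rdname ascent_catalog_io
#' @export
write_ascent_csv <- function(x, path) {
  utils::write.csv(data.frame(date = format(x$date), n_climbers = x$n_climbers,
                              oxygenless = x$oxygenless),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname ascent_catalog_io
#' @export
read_ascent_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- data.frame(date = as.Date(df$date),
                    n_climbers = as.integer(df$n_climbers),
                    oxygenless = as.logical(df$oxygenless))
  if (any(out$n_climbers <= 0)) stopf("climber counts must be positive")
  class(out) <- c("ascent_catalog", "data.frame")
  out
}

#' Attach summit pressures to an ascent catalog
#'
#' Each ascent record receives the summit pressure of its date: the daily
#' mean over the local (UTC+5:45) day by default, or the instantaneous
#' value at a fixed local summit hour. Records whose dates are not
#' covered by the series are flagged (`pressure = NA`) and excluded from
#' downstream statistics with a warning.
#'
#' @param catalog an `ascent_catalog`.
#' @param series summit `pressure_series` (hourly).
#' @param method `"daily_mean"` or `"summit_hour"`.
#' @param summit_hour local hour used when `method = "summit_hour"`.
#' @return the catalog with a `pressure` column.
#' @export
join_pressures <- function(catalog, series,
                           method = c("daily_mean", "summit_hour"),
                           summit_hour = 9) {
  method <- match.arg(method)
  stopifnot(inherits(series, "pressure_series"))
  if (method == "daily_mean") {
    dm <- daily_means(series)
    p <- dm$pressure[match(catalog$date, dm$date)]
  } else {
    # local summit hour converted to UTC, snapped to the nearest series hour
    target <- as_utc(paste(format(catalog$date), sprintf("%02d:00", summit_hour))) -
      5.75 * 3600
    p <- series$pressure[match(round(as.numeric(target) / 3600) * 3600,
                               as.numeric(series$time))]
  }
  if (anyNA(p)) {
    warning(sprintf("%d ascent record(s) not covered by the series; flagged NA",
                    sum(is.na(p))), call. = FALSE)
  }
  catalog$pressure <- p
  catalog
}

#' Monthly ascent and pressure statistics table
#'
#' For each calendar month: the number of oxygenless summits and their
#' share of the total; the mean and range of hourly summit pressure; the
#' percentage of hours exceeding the long-term annual mean and the mean
#' pressure across all oxygenless climbs; the mean pressure on oxygenless
#' climb days; and the percentile of that mean within the month's hourly
#' pressure distribution. Months with no oxygenless ascents leave the
#' climbing columns `NA`.
#'
#' @param catalog a joined catalog (see [join_pressures()]).
#' @param series hourly summit `pressure_series`.
#' @param annual_mean reference long-term mean, hPa (default: computed
#'   from the series).
#' @param climbing_mean reference mean across oxygenless climbs, hPa
#'   (default: climber-weighted mean of the joined oxygenless pressures).
#' @return a `monthly_stats` data.frame with one row per month.
#' @export
monthly_table <- function(catalog, series, annual_mean = NULL,
                          climbing_mean = NULL) {
  stopifnot(inherits(series, "pressure_series"), "pressure" %in% names(catalog))
  hp <- series$pressure[!is.na(series$pressure)]
  hmo <- (as.POSIXlt(series$time, tz = "UTC")$mon + 1L)[!is.na(series$pressure)]
  annual_mean <- annual_mean %||% mean(hp)
  ox <- catalog[catalog$oxygenless & !is.na(catalog$pressure), ]
  climbing_mean <- climbing_mean %||%
    stats::weighted.mean(ox$pressure, ox$n_climbers)
  total_ox <- sum(ox$n_climbers)
  cmo <- as.integer(format(ox$date, "%m"))

  rows <- lapply(1:12, function(m) {
    h <- hp[hmo == m]
    n_ox <- sum(ox$n_climbers[cmo == m])
    climb_p <- if (n_ox > 0)
      stats::weighted.mean(ox$pressure[cmo == m], ox$n_climbers[cmo == m])
      else NA_real_
    data.frame(
      month = m,
      summits = n_ox,
      summits_pct = 100 * n_ox / total_ox,
      mean_pressure = mean(h),
      pressure_range = max(h) - min(h),
      exceed_annual_mean_pct = 100 * mean(h > annual_mean),
      exceed_climbing_mean_pct = 100 * mean(h > climbing_mean),
      climbing_pressure = climb_p,
      climbing_pressure_percentile = if (n_ox > 0) 100 * mean(h < climb_p)
                                     else NA_real_
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "annual_mean") <- annual_mean
  attr(out, "climbing_mean") <- climbing_mean
  class(out) <- c("monthly_stats", "data.frame")
  out
}

#' Day-of-year pressure anomalies of ascents
#'
#' Ascent-day pressure minus the smoothed day-of-year climatology mean;
#' reports per-ascent anomalies and the climber-weighted catalog mean
#' (climbers favouring high-pressure windows for the time of year show a
#' positive mean anomaly).
#'
#' @param catalog a joined catalog.
#' @param climatology a [doy_climatology()] of the summit series.
#' @return list with `per_ascent` (catalog plus `anomaly`) and
#'   `mean_anomaly` (hPa, weighted by climber counts).
#' @export
anomaly_vs_doy <- function(catalog, climatology) {
  stopifnot("pressure" %in% names(catalog))
  doy <- doy365(as.POSIXct(paste(format(catalog$date), "12:00"), tz = "UTC"))
  anom <- catalog$pressure - climatology$mean[doy]
  keep <- !is.na(anom)
  list(per_ascent = cbind(catalog, anomaly = anom),
       mean_anomaly = stats::weighted.mean(anom[keep], catalog$n_climbers[keep]))
}
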