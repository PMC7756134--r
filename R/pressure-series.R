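#' Hourly (or regularly sampled) air pressure series
#'
#' The basic container used throughout the package: a data frame with a
#' UTC `time` column and a `pressure` column in hPa, carrying the station
#' or reconstruction elevation and a free-text source label as attributes.
#' Missing observations are kept as explicit `NA` rows rather than being
#' dropped, so gaps remain visible to every downstream operation.
#'
#' @param time POSIXct (UTC) timestamps, strictly increasing.
#' @param pressure numeric pressure in hPa; `NA` marks a missing value.
#'   Non-missing values must lie in the physically plausible range
#'   250--1100 hPa.
#' @param elevation elevation label in metres.
#' @param source free-text provenance label.
#' @return a `pressure_series` (also a `data.frame`).
#' @export
pressure_series <- function(time, pressure, elevation = NA_real_,
                            source = "unknown") {
  time <- as_utc(time)
  if (length(time) != length(pressure)) {
    stopf("time and pressure must have equal length")
  }
  if (anyNA(time)) stopf("timestamps must not be NA")
  if (is.unsorted(as.numeric(time), strictly = TRUE)) {
    stopf("timestamps must be strictly increasing")
  }
  ok <- is.na(pressure) | (pressure >= 250 & pressure <= 1100)
  if (!all(ok)) {
    stopf("pressure outside plausible range [250, 1100] hPa at %d point(s)",
          sum(!ok))
  }
  out <- data.frame(time = time, pressure = as.numeric(pressure))
  attr(out, "elevation") <- as.numeric(elevation)
  attr(out, "source") <- source
  class(out) <- c("pressure_series", "data.frame")
  out
}

#' @export
print.pressure_series <- function(x, ...) {
  cat(sprintf("<pressure_series> %d rows, elevation %s m, source: %s\n",
              nrow(x), format(attr(x, "elevation")), attr(x, "source")))
  cat(sprintf("  %s .. %s UTC; %d missing\n",
              format(min(x$time)), format(max(x$time)), sum(is.na(x$pressure))))
  cat(sprintf("  pressure: %.1f .. %.1f hPa (mean %.1f)\n",
              min(x$pressure, na.rm = TRUE), max(x$pressure, na.rm = TRUE),
              mean(x$pressure, na.rm = TRUE)))
  invisible(x)
}

#' Read / write a pressure series as CSV
#'
#' CSV layout is `timestamp,pressure_hPa` with ISO-8601 UTC timestamps.
#'
#' @param x a `pressure_series`.
#' @param path file path.
#' @rdname pressure_series_io
#' @export
write_pressure_csv <- function(x, path) {
  stopifnot(inherits(x, "pressure_series"))
  df <- data.frame(
    timestamp = format(x$time, "%Y-%m-%dT%H:%M:%SZ"),
    pressure_hPa = x$pressure
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @param elevation,source passed to [pressure_series()] on read.
#' @rdname pressure_series_io
#' @export
read_pressure_csv <- function(path, elevation = NA_real_, source = path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("timestamp", "pressure_hPa") %in% names(df))) {
    stopf("expected columns 'timestamp,pressure_hPa' in %s", path)
  }
  pressure_series(as_utc(df$timestamp), as.numeric(df$pressure_hPa),
                  elevation = elevation, source = source)
}

# Inner-join two series on time, keeping pairwise-complete rows only.
#' @noRd
overlap_pairs <- function(a, b) {
  m <- match(as.numeric(a$time), as.numeric(b$time))
  keep <- !is.na(m) & !is.na(a$pressure) & !is.na(b$pressure[m])
  data.frame(time = a$time[keep], a = a$pressure[keep], b = b$pressure[m[keep]])
}
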