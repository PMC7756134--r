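# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
as_utc <- function(x) {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- "UTC"
    return(x)
  }
  if (is.character(x) && length(x) && grepl("T", x[1], fixed = TRUE)) {
    return(as.POSIXct(sub("Z$", "", x), tz = "UTC",
                      format = "%Y-%m-%dT%H:%M:%S"))
  }
  as.POSIXct(x, tz = "UTC")
}

# Day of year on a fixed 365-day circle; Feb 29 folds into day 59 so that
# climatologies and kernel weights are leap-year invariant.
#' @noRd
doy365 <- function(time) {
  lt <- as.POSIXlt(time, tz = "UTC")
  doy <- lt$yday + 1L
  leap <- (lt$year + 1900L) %% 4L == 0L &
    ((lt$year + 1900L) %% 100L != 0L | (lt$year + 1900L) %% 400L == 0L)
  doy[leap & doy >= 60L] <- doy[leap & doy >= 60L] - 1L
  doy
}

# Circular Gaussian smoothing of a vector indexed on a closed ring
# (day-of-year axis). sigma in index units; sigma <= 0 returns x unchanged.
#' @noRd
smooth_circular <- function(x, sigma, period = length(x)) {
  if (sigma <= 0) return(x)
  idx <- seq_len(period)
  d <- abs(outer(idx, idx, "-"))
  d <- pmin(d, period - d)
  w <- exp(-0.5 * (d / sigma)^2)
  w <- w / rowSums(w)
  as.numeric(w %*% x)
}

# Deterministic per-stage substream seed derived from a root seed, kept
# below 2^31 so it is a valid R integer seed.
#' @noRd
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

# Seasonal weight on [0, 1]: 1 at mid-January (day 15), 0 at mid-July.
# Used to interpolate winter/summer noise levels.
#' @noRd
winter_weight <- function(doy) (1 + cos(2 * pi * (doy - 15) / 365.25)) / 2

#' @noRd
stopf <- function(...) stop(sprintf(...), call. = FALSE)
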