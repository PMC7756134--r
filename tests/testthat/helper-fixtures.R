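# Shared fixtures, built once per test file and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixtures[[name]])) assign(name, expr, envir = .fixtures)
  .fixtures[[name]]
}

# Default study conditions: 41 years of hourly summit pressure.
default_sim <- function() {
  fixture("default_sim", generate_summit_series(synthetic_config()))
}

default_fields <- function() {
  fixture("default_fields",
          generate_level_fields(default_sim()$series, config = synthetic_config()))
}

default_reconstruction <- function() {
  fixture("default_rec",
          reconstruct_summit_series(default_fields(), 8850))
}

default_climatology <- function() {
  fixture("default_clim", doy_climatology(default_reconstruction()))
}

# Truth-known low-noise fixture for event/transit recovery: noise an
# order of magnitude below the injected event depth.
low_noise_config <- function(seed = 7) {
  synthetic_config(sigma_winter = 0.2, sigma_summer = 0.1, seed = seed)
}

low_noise_sim <- function() {
  fixture("low_noise_sim", generate_summit_series(low_noise_config()))
}

# A short flat series with a pressure_series wrapper, for unit fixtures.
flat_series <- function(value = 330, days = 800, start = "2000-01-01") {
  time <- seq(as.POSIXct(start, tz = "UTC"), by = 3600,
              length.out = days * 24)
  pressure_series(time, rep(value, length(time)), elevation = 8850,
                  source = "flat fixture")
}

# Pure seasonal sinusoid series (no noise, no events).
sinusoid_series <- function(years = 3, mean = 331, amp = 8, phase = 214) {
  time <- seq(as.POSIXct("2001-01-01", tz = "UTC"),
              as.POSIXct(sprintf("%d-12-31 23:00", 2000 + years), tz = "UTC"),
              by = 3600)
  doy <- as.POSIXlt(time, tz = "UTC")$yday + 1
  pressure_series(time, mean + amp * cos(2 * pi * (doy - phase) / 365.25),
                  elevation = 8850, source = "sinusoid fixture")
}
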