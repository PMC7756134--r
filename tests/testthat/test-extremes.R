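test_that("single minimum of a monotone series is its final timestamp", {
  time <- seq(as.POSIXct("2000-01-01", tz = "UTC"), by = 3600, length.out = 200)
  s <- pressure_series(time, seq(340, 330, length.out = 200))
  ev <- suppressWarnings(find_lowest_events(s, n = 1))
  expect_identical(ev$time, time[200])
})

test_that("exclusion window keeps equal minima apart", {
  time <- seq(as.POSIXct("2000-01-01", tz = "UTC"), by = 3600,
              length.out = 30 * 24)
  p <- rep(335, length(time))
  p[10 * 24] <- 320
  p[13 * 24] <- 320   # 3 days later
  s <- pressure_series(time, p)
  ev <- find_lowest_events(s, n = 2, min_separation_days = 10)
  expect_identical(sum(ev$pressure == 320), 1L)  # second minimum excluded
  expect_identical(ev$time[1], time[10 * 24])
  # with a smaller window both minima qualify
  ev2 <- find_lowest_events(s, n = 2, min_separation_days = 2)
  expect_identical(sum(ev2$pressure == 320), 2L)
  # a series shorter than the window cannot supply two separable events
  short <- pressure_series(time[1:(5 * 24)], p[1:(5 * 24)])
  expect_warning(ev3 <- find_lowest_events(short, n = 2,
                                           min_separation_days = 10),
                 "separable")
  expect_identical(nrow(ev3), 1L)
})

test_that("event selection is deterministic and chunk-invariant", {
  s <- default_sim()$series
  a <- find_lowest_events(s, 20)
  b <- find_lowest_events(s, 20)
  expect_identical(a, b)
  # pressures in selection order are ascending
  expect_true(all(diff(a$pressure) >= 0))
  expect_true(all(diff(sort(as.numeric(a$time))) >= 10 * 86400))
})

test_that("injected events are recovered at their true times", {
  sim <- low_noise_sim()
  ev <- find_lowest_events(sim$series, 20)
  tt <- as.numeric(sim$truth$event_times)
  err_h <- vapply(as.numeric(ev$time),
                  function(e) min(abs(e - tt)) / 3600, numeric(1))
  expect_true(all(err_h <= 6))
})

test_that("composite of a single spike isolates the spike", {
  s <- flat_series(330, days = 800)
  clim <- doy_climatology(s)
  p <- s$pressure
  i0 <- 400 * 24
  p[i0] <- 320
  spiked <- pressure_series(s$time, p)
  ev <- structure(data.frame(time = s$time[i0], pressure = 320, month = 1),
                  class = c("event_set", "data.frame"))
  comp <- composite_anomalies(spiked, ev, window_days = 2, climatology = clim)
  expect_equal(comp$mean[comp$lag_hours == 0], -10)
  expect_equal(max(abs(comp$mean[comp$lag_hours != 0])), 0)
  expect_equal(comp$sd, rep(0, length(comp$lag_hours)))
})

test_that("composite of a pure climatology series is zero", {
  s <- sinusoid_series(years = 3)
  clim <- doy_climatology(s, sigma_days = 0)
  ev <- find_lowest_events(s, 2, min_separation_days = 30)
  comp <- composite_anomalies(s, ev, window_days = 5, climatology = clim)
  expect_lt(max(abs(comp$mean)), 0.05)
})

test_that("composite recovers injected event depth and recovery time", {
  cfg <- synthetic_config(events_per_winter = 1, sigma_winter = 0.5,
                          sigma_summer = 0.2, seed = 9)
  sim <- generate_summit_series(cfg)
  ev <- structure(data.frame(time = sim$truth$event_times),
                  class = c("event_set", "data.frame"))
  comp <- composite_anomalies(sim$series, ev,
                              climatology = doy_climatology(sim$series))
  depth <- min(comp$mean)
  expect_gte(depth, -11)
  expect_lte(depth, -9)
  expect_equal(comp$lag_hours[which.min(comp$mean)], 0)
  # recovery to half depth within 1-3 days after the minimum
  after <- comp$lag_hours > 0
  first_half <- min(comp$lag_hours[after & comp$mean >= depth / 2]) / 24
  expect_gte(first_half, 1)
  expect_lte(first_half, 3)
})

test_that("composite at random times is statistically flat", {
  s <- default_sim()$series
  clim <- default_climatology()
  set.seed(101)
  idx <- sort(sample(seq(2000, nrow(s) - 2000), 30))
  ev <- structure(data.frame(time = s$time[idx]),
                  class = c("event_set", "data.frame"))
  comp <- composite_anomalies(s, ev, climatology = clim)
  pointwise_se <- mean(comp$sd) / sqrt(comp$n_events)
  expect_lt(max(abs(comp$mean)), 4 * pointwise_se)
})

test_that("events without full window coverage are excluded with warning", {
  s <- flat_series(330, days = 800)
  clim <- doy_climatology(s)
  ev <- structure(data.frame(time = s$time[c(5, 400 * 24)]),
                  class = c("event_set", "data.frame"))
  expect_warning(comp <- composite_anomalies(s, ev, climatology = clim),
                 "coverage")
  expect_identical(comp$n_events, 1L)
})

test_that("phase speed is recovered within 2% across the speed range", {
  for (c0 in c(5, 10, 15, 25)) {
    cfg <- synthetic_config(phase_speed_ms = c0)
    f <- generate_level_fields(low_noise_sim()$series, config = cfg)
    hov <- generate_hovmoller(f, "1990-01-05", "1990-01-11")
    est <- estimate_phase_speed(hov)
    expect_true(est$coherent)
    expect_true(est$propagating)
    expect_lt(abs(est$phase_speed_ms / c0 - 1), 0.02)
  }
})

test_that("a stationary wave is flagged non-propagating", {
  f <- generate_level_fields(low_noise_sim()$series,
                             config = synthetic_config(phase_speed_ms = 0))
  hov <- generate_hovmoller(f, "1990-01-05", "1990-01-11")
  est <- estimate_phase_speed(hov)
  expect_false(est$propagating)
  expect_true(is.na(est$transit_days))
})

test_that("doubling the wavelength at fixed speed doubles the transit time", {
  s <- low_noise_sim()$series
  f1 <- generate_level_fields(s, config = synthetic_config(wavelength_km = 3000))
  f2 <- generate_level_fields(s, config = synthetic_config(wavelength_km = 6000))
  e1 <- estimate_phase_speed(generate_hovmoller(f1, "1990-01-05", "1990-01-11"))
  e2 <- estimate_phase_speed(generate_hovmoller(f2, "1990-01-05", "1990-01-11"))
  expect_equal(e2$transit_days / e1$transit_days, 2, tolerance = 1e-6)
})

test_that("transit time equals half wavelength over speed on fixtures", {
  f <- generate_level_fields(low_noise_sim()$series,
                             config = synthetic_config(phase_speed_ms = 10,
                                                       wavelength_km = 6000))
  hov <- generate_hovmoller(f, "1990-01-05", "1990-01-11")
  est <- estimate_phase_speed(hov)
  expect_equal(est$transit_days,
               (est$wavelength_m / 2) / est$phase_speed_ms / 86400,
               tolerance = 1e-9)
  expect_equal(est$transit_days, 3.5, tolerance = 0.15)
})

test_that("covariate correlation handles trivial and degenerate cases", {
  s <- default_sim()$series
  expect_equal(pressure_covariate_correlation(s, s$pressure), 1)
  expect_equal(pressure_covariate_correlation(s, -s$pressure), -1)
  expect_warning(r <- pressure_covariate_correlation(s, rep(5, nrow(s))),
                 "zero variance")
  expect_true(is.na(r))
  expect_error(pressure_covariate_correlation(s, s$pressure, months = integer(0)),
               "samples")
})

test_that("winter pressure-temperature and pressure-wind correlations emerge", {
  f <- default_fields()
  s <- default_sim()$series
  r_t <- pressure_covariate_correlation(s, f$temperature)
  r_u <- pressure_covariate_correlation(s, f$wind)
  expect_lt(abs(r_t - 0.8), 0.05)
  expect_lt(abs(r_u - (-0.1)), 0.05)
})
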