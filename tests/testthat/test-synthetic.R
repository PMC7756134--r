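test_that("zero-noise, zero-event series equals the pure seasonal cycle", {
  cfg <- synthetic_config(sigma_winter = 0, sigma_summer = 0,
                          events_per_winter = 0,
                          start = "2000-01-01", end = "2002-12-31 23:00")
  s <- generate_summit_series(cfg)$series
  doy <- thickair:::doy365(s$time)
  expected <- cfg$seasonal_mean +
    cfg$seasonal_amplitude * cos(2 * pi * (doy - cfg$seasonal_phase_day) / 365.25)
  expect_equal(s$pressure, expected, tolerance = 0)
})

test_that("generation is bitwise deterministic in the seed", {
  cfg <- synthetic_config(start = "2000-01-01", end = "2001-12-31 23:00", seed = 42)
  a <- generate_summit_series(cfg)
  b <- generate_summit_series(cfg)
  expect_identical(a$series$pressure, b$series$pressure)
  expect_identical(a$truth$event_times, b$truth$event_times)
  c <- generate_summit_series(synthetic_config(start = "2000-01-01",
                                               end = "2001-12-31 23:00",
                                               seed = 43))
  expect_false(identical(a$series$pressure, c$series$pressure))
})

test_that("config invariants are enforced", {
  expect_error(synthetic_config(sigma_winter = 1, sigma_summer = 2), "winter")
  expect_error(synthetic_config(sigma_winter = -1, sigma_summer = -2), "non-negative")
  expect_error(synthetic_config(aws_gap_fraction = 1), "gap")
  expect_error(synthetic_config(start = "2010-01-01", end = "2000-01-01"), "period")
  expect_error(synthetic_config(month_weights = rep(1, 12)), "weights")
  expect_error(synthetic_config(total_ascents = 10, oxygenless_ascents = 11),
               "oxygenless")
})

test_that("default January mean sits at the winter minimum near 323 hPa", {
  s <- default_sim()$series
  lt <- as.POSIXlt(s$time, tz = "UTC")
  jan_means <- tapply(s$pressure[lt$mon == 0], (lt$year + 1900)[lt$mon == 0], mean)
  se <- stats::sd(jan_means) / sqrt(length(jan_means))
  expect_lt(abs(mean(jan_means) - 323), 2 * se)
  aug <- mean(s$pressure[lt$mon == 7])
  expect_lt(abs(aug - 339), 1)
})

test_that("winter variability exceeds summer variability when configured so", {
  s <- default_sim()$series
  lt <- as.POSIXlt(s$time, tz = "UTC")
  res <- s$pressure - thickair:::seasonal_cycle_at(synthetic_config(),
                                                   thickair:::doy365(s$time))
  expect_gt(stats::sd(res[lt$mon %in% c(11, 0, 1)]),
            stats::sd(res[lt$mon %in% 5:7]))
})

test_that("noiseless level fields reproduce the summit truth by extrapolation", {
  s <- low_noise_sim()$series
  f <- generate_level_fields(s, config = low_noise_config())
  rec <- reconstruct_summit_series(f, 8850)
  expect_lt(max(abs(rec$pressure - s$pressure)), 1e-9)
})

test_that("prescribed covariate correlations are recovered in winter samples", {
  cfg <- synthetic_config()
  f <- default_fields()
  s <- default_sim()$series
  mo <- as.POSIXlt(s$time, tz = "UTC")$mon + 1
  win <- which(mo %in% c(12, 1, 2))[1:10000]
  r_t <- stats::cor(s$pressure[win], f$temperature[win])
  r_u <- stats::cor(s$pressure[win], f$wind[win])
  expect_lt(abs(r_t - cfg$temp_cor), 0.05)
  expect_lt(abs(r_u - cfg$wind_cor), 0.05)
})

test_that("level fields reject a summit outside the bracketing levels", {
  s <- flat_series(330, days = 10)
  expect_error(generate_level_fields(s, levels = c(320, 300)), "bracketing")
})

test_that("AWS generator is exact when offset, noise and gaps are zero", {
  s <- flat_series(330, days = 30)
  aws <- generate_aws_series(s, 7945, offset = 0, sigma = 0, gap_fraction = 0)
  expect_equal(aws$pressure,
               extrapolate_pressure(s$pressure, 8850, 7945, 1.4e-4))
})

test_that("AWS gap thinning removes exactly the configured fraction", {
  s <- flat_series(330, days = 100)
  aws <- generate_aws_series(s, 7945, gap_fraction = 0.3, seed = 3)
  n <- nrow(s)
  expect_identical(sum(!is.na(aws$pressure)), n - as.integer(round(0.3 * n)))
  # gaps come in contiguous blocks, not isolated hours
  gaps <- rle(is.na(aws$pressure))
  expect_gt(mean(gaps$lengths[gaps$values]), 3)
})

test_that("injected AWS offset is recovered by the mean difference", {
  s <- flat_series(335, days = 250)   # > 5000 hourly points
  aws <- generate_aws_series(s, 7945, offset = 1.5, sigma = 0.2,
                             gap_fraction = 0, seed = 11)
  truth_at_station <- extrapolate_pressure(s$pressure, 8850, 7945, 1.4e-4)
  expect_lt(abs(mean(aws$pressure - truth_at_station) - 1.5), 0.05)
})

test_that("noiseless ensemble member recovers its sensitivity exactly", {
  cfg <- synthetic_config(n_models = 2, sensitivity_mean = 2.5,
                          sensitivity_sd = 0, monthly_noise_sd = 0,
                          temp_noise_sd = 0, winter_amplification = 0)
  ens <- generate_cmip_ensemble(cfg)
  sens <- cmip_sensitivity(ens, "mean")
  expect_equal(unname(sens$median), 2.5, tolerance = 1e-8)
})

test_that("ensemble generator refuses too-short records", {
  expect_error(generate_cmip_ensemble(
    synthetic_config(ens_start_year = 2000, ens_end_year = 2020)), "31 years")
})

test_that("constant warming path is flagged as a degenerate regressor", {
  cfg <- synthetic_config(warming_rate_per_decade = 0, temp_noise_sd = 0)
  ens <- generate_cmip_ensemble(cfg)
  expect_error(suppressWarnings(cmip_sensitivity(ens, "mean")), "degenerate")
})

test_that("ascent catalog honours totals and the printed oxygenless share", {
  cfg <- synthetic_config()
  catalog <- fixture("default_catalog",
                     generate_ascent_catalog(cfg, default_sim()$series))
  expect_identical(sum(catalog$n_climbers), 10068L)
  expect_identical(sum(catalog$n_climbers[catalog$oxygenless]), 208L)
  share <- 100 * sum(catalog$n_climbers[catalog$oxygenless]) / sum(catalog$n_climbers)
  expect_identical(sprintf("%.1f", share), "2.1")
})

test_that("month weights concentrated on May date every ascent in May", {
  w <- c(0, 0, 0, 0, 1, 0, 0, 0, 0, 0, 0, 0)
  cfg <- synthetic_config(total_ascents = 50, oxygenless_ascents = 5,
                          month_weights = w, seed = 5)
  catalog <- generate_ascent_catalog(cfg, default_sim()$series)
  expect_true(all(format(catalog$date, "%m") == "05"))
})

test_that("oxygenless climb days are biased toward the configured percentile", {
  catalog <- fixture("default_catalog",
                     generate_ascent_catalog(synthetic_config(),
                                             default_sim()$series))
  dm <- thickair:::daily_means(default_sim()$series)
  dm$month <- as.integer(format(dm$date, "%m"))
  ox_may <- catalog[catalog$oxygenless & format(catalog$date, "%m") == "05", ]
  may <- dm[dm$month == 5 & !is.na(dm$pressure), ]
  day_p <- may$pressure[match(ox_may$date, may$date)]
  pct <- rep(100 * stats::ecdf(may$pressure)(day_p), ox_may$n_climbers)
  expect_lt(abs(mean(pct) - 70), 5)
})

test_that("truth record reaches YAML with its seed and event times", {
  sim <- generate_summit_series(synthetic_config(start = "2000-01-01",
                                                 end = "2001-12-31 23:00"))
  path <- tempfile(fileext = ".yaml")
  write_truth_yaml(sim$truth, path)
  back <- yaml::read_yaml(path)
  expect_identical(back$seed, 1L)
  expect_length(back$event_times, length(sim$truth$event_times))
})
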