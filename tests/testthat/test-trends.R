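test_that("Theil-Sen recovers an exact line with zero-width bounds", {
  yrs <- 1979:2019
  tr <- theil_sen(yrs, 0.05 * yrs + 12)
  expect_equal(tr$slope, 0.5, tolerance = 1e-12)
  expect_equal(tr$lower, 0.5, tolerance = 1e-12)
  expect_equal(tr$upper, 0.5, tolerance = 1e-12)
})

test_that("Theil-Sen equals the brute-force pairwise oracle", {
  brute <- function(x, y, probs = c(0.05, 0.95)) {
    s <- c()
    for (i in seq_along(x)) {
      for (j in seq_along(x)) {
        if (j > i && x[j] != x[i]) s <- c(s, (y[j] - y[i]) / (x[j] - x[i]))
      }
    }
    c(median = stats::median(s), stats::quantile(s, probs, names = FALSE))
  }
  set.seed(5)
  x6 <- 2001:2006
  y6 <- c(330.2, 331.0, 330.1, 332.4, 331.7, 333.0)
  tr <- theil_sen(x6, y6)
  or <- brute(x6, y6)
  expect_equal(tr$slope, 10 * or[["median"]], tolerance = 1e-12)

  for (k in 1:6) {
    n <- sample(5:50, 1)
    x <- sort(sample(1960:2020, n))
    y <- 0.03 * x + rnorm(n, 0, 2)
    tr <- theil_sen(x, y)
    or <- brute(x, y)
    expect_equal(tr$slope, 10 * or[[1]], tolerance = 1e-12)
    expect_equal(tr$lower, 10 * or[[2]], tolerance = 1e-12)
    expect_equal(tr$upper, 10 * or[[3]], tolerance = 1e-12)
    expect_true(tr$lower <= tr$slope && tr$slope <= tr$upper)
  }
})

test_that("Theil-Sen is location-invariant and robust to <29% corruption", {
  yrs <- 2000:2019
  vals <- 0.04 * yrs + 5
  base <- theil_sen(yrs, vals)
  shifted <- theil_sen(yrs, vals + 100)
  expect_equal(base$slope, shifted$slope, tolerance = 1e-12)
  corrupted <- vals
  corrupted[c(3, 8, 11, 15, 19)] <- corrupted[c(3, 8, 11, 15, 19)] + 50
  expect_equal(theil_sen(yrs, corrupted)$slope, base$slope, tolerance = 1e-12)
})

test_that("duplicate years are excluded from pairing", {
  tr <- theil_sen(c(2000, 2000, 2001, 2002), c(1, 5, 2, 3))
  expect_true(is.finite(tr$slope))
  expect_error(theil_sen(c(2000, 2000, 2000), c(1, 2, 3)), "duplicated")
})

test_that("trend-to-sensitivity conversion is a plain ratio", {
  tr <- list(slope = 0.35, lower = 0.23, upper = 0.48, statistic = "annual mean")
  class(tr) <- "trend_result"
  s <- trend_to_sensitivity(tr, 0.17)
  expect_equal(s$median, 0.35 / 0.17, tolerance = 1e-12)
  expect_equal(s$median, 2.06, tolerance = 0.01)
  expect_equal(trend_to_sensitivity(0, 0.17)$median, 0)
  expect_equal(trend_to_sensitivity(0.7, 0.17)$median,
               2 * trend_to_sensitivity(0.35, 0.17)$median, tolerance = 1e-12)
  expect_error(trend_to_sensitivity(tr, 0), "non-zero")
})

test_that("ensemble sensitivities recover injected values", {
  ens <- fixture("default_ens", generate_cmip_ensemble(synthetic_config()))
  truth <- ens$truth$sensitivities
  s <- cmip_sensitivity(ens, "mean")
  expect_lt(abs(s$median - stats::median(truth)), 0.15)
  expect_true(s$lower <= s$median && s$median <= s$upper)
  expect_true(all(is.finite(s$per_model)))
})

test_that("winter-amplified response makes the annual minimum most sensitive", {
  ens <- fixture("default_ens", generate_cmip_ensemble(synthetic_config()))
  s_min <- cmip_sensitivity(ens, "min")
  s_max <- cmip_sensitivity(ens, "max")
  s_mean <- cmip_sensitivity(ens, "mean")
  expect_gt(s_min$median, s_mean$median)
  expect_gt(s_mean$median, s_max$median)
})

test_that("projection is linear with correct implied elevation change", {
  vo2 <- calibrate_vo2_model()
  pr0 <- project_stat(309, 2.5, 0, vo2)
  expect_equal(pr0$projected_hPa, 309)
  expect_equal(pr0$apparent_elevation_change_m, 0)
  pr2 <- project_stat(309, 2.5, 2, vo2)
  expect_equal(pr2$projected_hPa, 314)
  expect_equal(pr2$apparent_elevation_change_m, log(314 / 309) / 1.4e-4,
               tolerance = 1e-9)
  expect_equal(pr2$apparent_elevation_change_m, 115, tolerance = 1)
  expect_gt(pr2$vo2_change_pct, 0)
  pr4 <- project_stat(309, 2.5, 4, vo2)
  expect_equal(pr4$projected_hPa - 309, 2 * (pr2$projected_hPa - 309),
               tolerance = 1e-12)
  expect_false(pr2$extrapolated)
  expect_true(project_stat(309, 2.5, 5)$extrapolated)
})

test_that("warming-to-threshold inverts projection", {
  expect_equal(warming_to_threshold(331, 331, 2.56), 0)
  expect_equal(warming_to_threshold(312.6, 331, 2.56), (331 - 312.6) / 2.56,
               tolerance = 1e-12)
  expect_equal(warming_to_threshold(312.6, 331, 5.12),
               warming_to_threshold(312.6, 331, 2.56) / 2, tolerance = 1e-12)
  # cooling scenario: target below current is negative warming
  expect_lt(warming_to_threshold(314.5, 302, 2.56), 0)
  expect_error(warming_to_threshold(310, 320, 0), "positive")
  dT <- warming_to_threshold(309, 320, 2.2)
  expect_equal(project_stat(309, 2.2, dT)$projected_hPa, 320, tolerance = 1e-12)
})

test_that("decadal distribution shift detects identical and shifted decades", {
  s <- default_sim()$series
  same <- decadal_distribution_shift(s, c(1985, 1994), c(1985, 1994))
  expect_equal(same$difference, rep(0, nrow(same)))
  shifted <- pressure_series(s$time,
                             s$pressure + ifelse(
                               as.POSIXlt(s$time, tz = "UTC")$year + 1900 >= 2010,
                               1, 0))
  d <- decadal_distribution_shift(shifted, c(1979, 1988), c(2010, 2019))
  base <- decadal_distribution_shift(s, c(1979, 1988), c(2010, 2019))
  expect_equal(d$difference - base$difference, rep(1, nrow(d)), tolerance = 1e-9)
  expect_error(decadal_distribution_shift(s, c(1979, 1988), c(2015, 2024)),
               "covered")
})

test_that("a monsoon-only shift moves monsoon medians but not winter medians", {
  s <- default_sim()$series
  mo <- as.POSIXlt(s$time, tz = "UTC")$mon + 1
  late <- as.POSIXlt(s$time, tz = "UTC")$year + 1900 >= 2010
  bump <- ifelse(late & mo %in% 6:9, 2, 0)
  shifted <- pressure_series(s$time, s$pressure + bump)
  d <- decadal_distribution_shift(shifted, c(1979, 1988), c(2010, 2019))
  med <- d[d$prob == 0.5, ]
  base <- decadal_distribution_shift(s, c(1979, 1988), c(2010, 2019))
  base_med <- base[base$prob == 0.5, ]
  delta <- med$difference - base_med$difference
  expect_equal(delta[med$month %in% 6:9], rep(2, 4), tolerance = 1e-9)
  expect_equal(delta[med$month %in% c(12, 1, 2)], rep(0, 3), tolerance = 1e-9)
})

test_that("true trends fall inside the reported bounds in seeded replicates", {
  # interannual noise level taken from the default generated climate
  s <- default_sim()$series
  yr <- as.POSIXlt(s$time, tz = "UTC")$year + 1900
  ann <- tapply(s$pressure, yr, mean)
  sigma <- stats::sd(ann)
  set.seed(2024)
  yrs <- 1979:2019
  true_slope <- 0.035    # hPa per year
  hits <- 0
  n_rep <- 200
  for (r in seq_len(n_rep)) {
    y <- 330 + true_slope * (yrs - 1979) + rnorm(length(yrs), 0, sigma)
    tr <- theil_sen(yrs, y)
    if (tr$lower <= 10 * true_slope && 10 * true_slope <= tr$upper) {
      hits <- hits + 1
    }
  }
  expect_gte(hits / n_rep, 0.9)
})
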