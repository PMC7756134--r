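#' Physiological reference constants
#'
#' Constants used by the pressure-to-physiology conversions: the dry-air
#' oxygen mole fraction, the mean May vertical gradient of log pressure at
#' the summit and the mean May summit pressure (the reference state for
#' apparent-elevation conversions), the reference summit VO2max, the lower
#' pressure limit for an oxygenless ascent of a very fit climber (sea-level
#' VO2max around 57 mL kg^-1 min^-1), and the ICAO Standard Atmosphere
#' coefficients.
#'
#' @return named list of constants.
#' @export
physio_constants <- function() {
  list(
    o2_fraction = 0.2095,           # dry-air O2 mole fraction
    gamma_may = 1.4e-4,             # May-mean d(ln p)/dz, m^-1
    p_may = 333,                    # May-mean summit pressure, hPa
    vo2_may = 16.2,                 # summit VO2max at 333 hPa, mL/kg/min
    summit_elevation = 8850,        # m
    oxygenless_threshold = 302,     # hPa
    vo2_sea_level = 57,             # mL/kg/min
    icao_p0 = 1013.25,              # hPa
    icao_lapse = 2.25577e-5,        # m^-1
    icao_exponent = 5.25588
  )
}

#' Default calibration anchors for the summit VO2max curve
#'
#' Four constraints pin the curve on the summit pressure range: an absolute
#' anchor (16.2 mL kg^-1 min^-1 at the May-mean 333 hPa) and three relative
#' reductions between notable pressures -- 8.1\% between 329 and 340 hPa,
#' 15.9\% between 309 and 329 hPa, and 24.0\% between 309 and 343 hPa
#' (the lowest and highest pressures of the 1979--2019 reconstruction and
#' the extremes encountered on oxygenless summit days).
#'
#' @return data.frame of linear constraints on the cubic coefficients,
#'   with columns `p`, `p_ref`, `ratio`, `value`. A row with finite
#'   `value` fixes `V(p) = value`; otherwise it fixes
#'   `V(p) = ratio * V(p_ref)`.
#' @export
vo2_default_anchors <- function() {
  data.frame(
    p     = c(333, 329, 309, 309),
    p_ref = c(NA, 340, 329, 343),
    ratio = c(NA, 1 - 0.081, 1 - 0.159, 1 - 0.240),
    value = c(16.2, NA, NA, NA)
  )
}

poly_row <- function(p) c(1, p, p^2, p^3)

#' Calibrate the pressure--VO2max model
#'
#' Fits a cubic polynomial `V(P)` on the summit pressure range by solving
#' the linear system implied by the anchor constraints (ratio constraints
#' are linear in the polynomial coefficients), then verifies that the
#' fitted curve is strictly increasing and positive on the validity range
#' (300--345 hPa). If the cubic were non-monotone, the model falls back to
#' a monotone piecewise-cubic interpolant through anchor-consistent node
#' values (scaled so the curve passes through 16.2 at 333 hPa).
#'
#' Above the summit range the model is extended to sea level by a monotone
#' Hermite interpolant through ICAO-anchored nodes: the pressures at
#' 3,169 m and 2,132 m in the ICAO Standard Atmosphere paired with 76.0\%
#' and 84.1\% of the sea-level VO2max (57 mL kg^-1 min^-1), and 57 at
#' 1013.25 hPa. The seam with the summit cubic at 343 hPa is continuous
#' by construction.
#'
#' @param anchors anchor table as returned by [vo2_default_anchors()].
#' @param constants see [physio_constants()].
#' @return an object of class `vo2_model`.
#' @export
calibrate_vo2_model <- function(anchors = vo2_default_anchors(),
                                constants = physio_constants()) {
  stopifnot(nrow(anchors) == 4)
  A <- matrix(0, 4, 4)
  b <- numeric(4)
  for (i in seq_len(4)) {
    if (!is.na(anchors$value[i])) {
      A[i, ] <- poly_row(anchors$p[i])
      b[i] <- anchors$value[i]
    } else {
      A[i, ] <- poly_row(anchors$p[i]) - anchors$ratio[i] * poly_row(anchors$p_ref[i])
      b[i] <- 0
    }
  }
  coefs <- tryCatch(solve(A, b), error = function(e) {
    stopf("VO2 calibration system is singular: %s", conditionMessage(e))
  })
  cubic <- function(p) drop(cbind(1, p, p^2, p^3) %*% coefs)

  grid <- seq(300, 345, by = 0.1)
  vals <- cubic(grid)
  method <- "cubic"
  summit_fun <- cubic
  if (any(diff(vals) <= 0) || any(vals <= 0)) {
    # Monotone fallback: node values are fixed ratios of V(343); the
    # interpolant is linear in that scale, so the absolute anchor at
    # 333 hPa fixes the scale directly.
    node_p <- c(309, 329, 340, 343)
    node_rel <- c(0.760, 0.760 / 0.841, (0.760 / 0.841) / 0.919, 1)
    f1 <- stats::splinefun(node_p, node_rel, method = "monoH.FC")
    scale <- constants$vo2_may / f1(constants$p_may)
    summit_fun <- function(p) scale * f1(p)
    vals <- summit_fun(grid)
    method <- "monotone-fallback"
    if (any(diff(vals) <= 0) || any(vals <= 0)) {
      stopf("VO2 calibration failed: fallback interpolant not monotone/positive")
    }
  }

  v343 <- summit_fun(343)
  ext_p <- c(343,
             icao_pressure(3169),
             icao_pressure(2132),
             constants$icao_p0)
  ext_v <- c(v343,
             0.760 * constants$vo2_sea_level,
             0.841 * constants$vo2_sea_level,
             constants$vo2_sea_level)
  ext_fun <- stats::splinefun(ext_p, ext_v, method = "monoH.FC")
  ext_grid <- seq(343, constants$icao_p0, length.out = 500)
  if (any(diff(ext_fun(ext_grid)) <= 0)) {
    stopf("VO2 full-range extension is not monotone")
  }

  structure(
    list(coefficients = coefs, method = method,
         summit_fun = summit_fun, ext_fun = ext_fun,
         range = c(300, constants$icao_p0), seam = 343,
         anchors = anchors, extension_nodes = cbind(p = ext_p, vo2 = ext_v),
         constants = constants),
    class = "vo2_model"
  )
}

#' @export
print.vo2_model <- function(x, ...) {
  cat(sprintf("<vo2_model> %s on [300, 343] hPa + monotone extension to %.2f hPa\n",
              x$method, x$range[2]))
  cat(sprintf("  V(333) = %.2f, V(343) = %.2f, V(1013.25) = %.2f mL/kg/min\n",
              vo2max(333, x), vo2max(343, x), vo2max(x$range[2], x)))
  invisible(x)
}

#' Maximal oxygen uptake at a given air pressure
#'
#' @param p air pressure in hPa; must lie in `[300, 1013.25]` (the model is
#'   not validated below 300 hPa).
#' @param model a [calibrate_vo2_model()] fit.
#' @return VO2max in mL kg^-1 min^-1, strictly increasing in `p`.
#' @export
vo2max <- function(p, model = calibrate_vo2_model()) {
  stopifnot(inherits(model, "vo2_model"))
  if (any(p < model$range[1] | p > model$range[2])) {
    stopf("pressure outside VO2 model range [%.0f, %.2f] hPa",
          model$range[1], model$range[2])
  }
  out <- numeric(length(p))
  lo <- p <= model$seam
  if (any(lo)) out[lo] <- model$summit_fun(p[lo])
  if (any(!lo)) out[!lo] <- model$ext_fun(p[!lo])
  out
}

#' Percentage VO2max reduction between two pressures
#'
#' `100 * (1 - V(p_low)/V(p_high))`; non-negative because the model is
#' increasing in pressure.
#'
#' @param p_low,p_high pressures in hPa with `p_low <= p_high`.
#' @inheritParams vo2max
#' @export
vo2_reduction_percent <- function(p_low, p_high, model = calibrate_vo2_model()) {
  if (any(p_low > p_high)) stopf("p_low must not exceed p_high")
  100 * (1 - vo2max(p_low, model) / vo2max(p_high, model))
}

#' Inspired oxygen partial pressure
#'
#' Dry-air proportionality: pO2 = 0.2095 * P, so oxygen partial pressure
#' rises by about 0.21 hPa for every 1 hPa of total pressure.
#'
#' @param p total air pressure, hPa (non-negative).
#' @export
o2_partial_pressure <- function(p) {
  if (any(p < 0)) stopf("pressure must be non-negative")
  physio_constants()$o2_fraction * p
}

#' Apparent (perceived) summit elevation for a given pressure
#'
#' Converts a summit pressure into the elevation at which that pressure
#' would be met on a reference mean May day: the pressure profile is
#' log-linear with the May-mean gradient (0.00014 m^-1) anchored at
#' 333 hPa on the 8,850 m summit. Returns the total apparent elevation
#' `z = 8850 + delta_z`; `delta_z` is negative when `p > 333`.
#'
#' @param p pressure in hPa (> 0).
#' @param constants see [physio_constants()].
#' @return data.frame with columns `pressure`, `delta_z`, `z` (metres).
#' @export
apparent_elevation <- function(p, constants = physio_constants()) {
  if (any(p <= 0)) stopf("pressure must be positive")
  dz <- log(constants$p_may / p) / constants$gamma_may
  data.frame(pressure = p, delta_z = dz, z = constants$summit_elevation + dz)
}

#' Calibrate the climbing-rate model
#'
#' Sustained vertical climbing rate is modelled as linear in VO2max above
#' a fixed overhead `b` (the oxygen cost of staying alive and upright that
#' buys no upward progress): `rate = k * (V(P) - b)` for the 100 kg
#' reference climber. The two parameters are pinned by the worked anchors:
#' 3.5 m min^-1 at 343 hPa and a 41.2\% reduction at 309 hPa. The 29.5\%
#' reduction between 329 and 309 hPa is then a parameter-free consequence.
#'
#' @param vo2_model a [calibrate_vo2_model()] fit.
#' @param rate_ref reference rate (m min^-1) at `p_ref` for `mass_ref`.
#' @param p_ref,p_low anchor pressures, hPa.
#' @param reduction fractional rate reduction at `p_low` relative `p_ref`.
#' @param mass_ref reference climber-plus-kit mass, kg.
#' @return an object of class `climb_model` with elements `b`
#'   (mL kg^-1 min^-1), `k` (m min^-1 per mL kg^-1 min^-1), `mass_ref`.
#' @export
calibrate_climb_model <- function(vo2_model = calibrate_vo2_model(),
                                  rate_ref = 3.5, p_ref = 343, p_low = 309,
                                  reduction = 0.412, mass_ref = 100) {
  v_ref <- vo2max(p_ref, vo2_model)
  v_low <- vo2max(p_low, vo2_model)
  b <- (v_low - (1 - reduction) * v_ref) / reduction
  k <- rate_ref / (v_ref - b)
  if (b <= 0 || k <= 0) stopf("climb calibration gave non-positive b or k")
  structure(list(b = b, k = k, mass_ref = mass_ref,
                 anchors = list(rate_ref = rate_ref, p_ref = p_ref,
                                p_low = p_low, reduction = reduction)),
            class = "climb_model")
}

#' @export
print.climb_model <- function(x, ...) {
  cat(sprintf("<climb_model> overhead b = %.3f mL/kg/min, k = %.4f m/min per mL/kg/min (ref mass %g kg)\n",
              x$b, x$k, x$mass_ref))
  invisible(x)
}

#' Sustainable vertical climbing rate
#'
#' Rate scales inversely with total mass (same aerobic power moving more
#' kilograms). When VO2max falls to the overhead `b` or below, the rate is
#' 0 and the result carries a `below_threshold` attribute flagging which
#' inputs were unsustainable.
#'
#' @param p pressure in hPa.
#' @param mass climber-plus-equipment mass, kg.
#' @param vo2_model,climb_model calibrated models.
#' @return rate in vertical m min^-1.
#' @export
climbing_rate <- function(p, mass = 100, vo2_model = calibrate_vo2_model(),
                          climb_model = calibrate_climb_model(vo2_model)) {
  if (any(mass <= 0)) stopf("mass must be positive")
  v <- vo2max(p, vo2_model)
  raw <- climb_model$k * (v - climb_model$b) * (climb_model$mass_ref / mass)
  out <- pmax(raw, 0)
  attr(out, "below_threshold") <- v <= climb_model$b
  out
}

#' Multiplicative time factor between two pressures
#'
#' How many times longer a fixed climb takes at pressure `p2` than at
#' pressure `p1`; `> 1` whenever `p2 < p1`. An unsustainable rate at `p2`
#' yields `Inf` with an `unsustainable` attribute.
#'
#' @param p1,p2 pressures in hPa.
#' @inheritParams climbing_rate
#' @export
climb_time_factor <- function(p1, p2, mass = 100,
                              vo2_model = calibrate_vo2_model(),
                              climb_model = calibrate_climb_model(vo2_model)) {
  r1 <- as.numeric(climbing_rate(p1, mass, vo2_model, climb_model))
  r2 <- as.numeric(climbing_rate(p2, mass, vo2_model, climb_model))
  if (any(r1 <= 0)) stopf("rate at p1 is zero; time factor undefined")
  out <- r1 / r2
  attr(out, "unsustainable") <- r2 <= 0
  out
}

#' ICAO Standard Atmosphere pressure at elevation
#'
#' `P(z) = 1013.25 * (1 - 2.25577e-5 z)^5.25588`, valid in the troposphere
#' (0--11,000 m); strictly decreasing in `z`.
#'
#' @param z elevation in metres.
#' @export
icao_pressure <- function(z) {
  if (any(z < 0 | z > 11000)) stopf("elevation outside tropospheric range [0, 11000] m")
  k <- physio_constants()
  k$icao_p0 * (1 - k$icao_lapse * z)^k$icao_exponent
}

#' ICAO-equivalent elevation for a fractional VO2max reduction
#'
#' The elevation one would need to ascend to, from sea level in the ICAO
#' Standard Atmosphere, for VO2max to fall to `fraction` of its sea-level
#' value. Solved by root finding on the full-range VO2 model.
#'
#' @param fraction target ratio `V(P(z)) / V(1013.25)` in (0, 1].
#' @inheritParams vo2max
#' @return elevation in metres.
#' @export
icao_equivalent_elevation <- function(fraction, model = calibrate_vo2_model()) {
  if (any(fraction <= 0 | fraction > 1)) stopf("fraction must be in (0, 1]")
  v0 <- vo2max(physio_constants()$icao_p0, model)
  k <- physio_constants()
  # highest elevation whose ICAO pressure is still inside the model range
  zmax <- (1 - (model$range[1] / k$icao_p0)^(1 / k$icao_exponent)) / k$icao_lapse
  vapply(fraction, function(f) {
    if (f == 1) return(0)
    g <- function(z) vo2max(icao_pressure(z), model) / v0 - f
    if (g(zmax) > 0) stopf("fraction %.3f below the model's attainable range", f)
    stats::uniroot(g, c(0, zmax), tol = 1e-6)$root
  }, numeric(1))
}

#' Is an oxygenless ascent feasible at this pressure?
#'
#' Feasibility against the ~302 hPa lower limit for a very fit climber;
#' the margin is the headroom in hPa (negative when infeasible).
#'
#' @param p pressure in hPa (> 0).
#' @param threshold feasibility threshold, hPa.
#' @return data.frame with `pressure`, `feasible`, `margin`.
#' @export
is_oxygenless_feasible <- function(p, threshold = physio_constants()$oxygenless_threshold) {
  if (any(p <= 0)) stopf("pressure must be positive")
  data.frame(pressure = p, feasible = p >= threshold, margin = p - threshold)
}

#' Physiology summary table for one or more pressures
#'
#' One row per pressure: inspired pO2, VO2max, apparent elevation, the
#' sustainable climbing rate for the given mass, and oxygenless
#' feasibility. With `compare` set, reduction percentages relative to the
#' comparison pressure are appended.
#'
#' @param p pressures in hPa.
#' @param mass climber mass in kg.
#' @param compare optional reference pressure for reduction columns.
#' @inheritParams climbing_rate
#' @export
physio_table <- function(p, mass = 100, compare = NULL,
                         vo2_model = calibrate_vo2_model(),
                         climb_model = calibrate_climb_model(vo2_model)) {
  ae <- apparent_elevation(p)
  out <- data.frame(
    pressure_hPa = p,
    pO2_hPa = o2_partial_pressure(p),
    vo2max = vo2max(p, vo2_model),
    apparent_elevation_m = ae$z,
    delta_z_m = ae$delta_z,
    climb_rate_m_min = as.numeric(climbing_rate(p, mass, vo2_model, climb_model)),
    oxygenless_feasible = is_oxygenless_feasible(p)$feasible
  )
  if (!is.null(compare)) {
    out$vo2_reduction_pct <- vo2_reduction_percent(pmin(p, compare),
                                                   pmax(p, compare), vo2_model)
    rc <- as.numeric(climbing_rate(compare, mass, vo2_model, climb_model))
    out$rate_reduction_pct <- 100 * (1 - out$climb_rate_m_min / rc)
  }
  out
}
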