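#' Run the full synthetic analysis pipeline
#'
#' End-to-end composition of the stages: simulate the synthetic inputs,
#' reconstruct summit pressure from the level fields with a station bias
#' adjustment, validate against the station, build the day-of-year
#' climatology, tabulate the physiology of notable pressures, detect and
#' composite the lowest-pressure events with wave transit estimates,
#' estimate trends and ensemble sensitivities with projections, and join
#' the ascent catalog. Outputs are written under `out_dir` (CSV for
#' tables and series, YAML for reports) together with a provenance block
#' (seed, key constants, package version); the returned list carries every
#' stage result. A stage whose inputs are unavailable is skipped with a
#' notice rather than failing the run.
#'
#' @param config a [synthetic_config()].
#' @param out_dir output directory, created if needed; `NULL` skips all
#'   file output.
#' @param n_events events for the extremes stage.
#' @param delta_T warming levels (deg C) for the projection stage.
#' @param catalog optional pre-built `ascent_catalog`; `NA` skips the
#'   ascents stage.
#' @return invisible list of stage results.
#' @export
run_pipeline <- function(config = synthetic_config(), out_dir = NULL,
                         n_events = 20, delta_T = c(1, 2),
                         catalog = NULL) {
  res <- list(config = config)
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  emit <- function(name, writer) {
    if (!is.null(out_dir)) writer(file.path(out_dir, name))
  }

  # --- simulate -----------------------------------------------------------
  sim <- generate_summit_series(config)
  truth <- sim$series
  fields <- generate_level_fields(truth, config = config)
  aws <- generate_aws_series(truth, config$station_elevation,
                             config$aws_offset_hPa, config$aws_sigma_hPa,
                             config$aws_gap_fraction, config$seed)
  res$truth <- sim$truth
  emit("summit_truth.csv", function(p) write_pressure_csv(truth, p))
  emit("aws.csv", function(p) write_pressure_csv(aws, p))
  emit("truth.yaml", function(p) write_truth_yaml(sim$truth, p))

  # --- reconstruct --------------------------------------------------------
  raw <- reconstruct_summit_series(fields, config$summit_elevation)
  aws_est <- pressure_series(raw$time,
                             extrapolate_pressure(raw$pressure,
                                                  config$summit_elevation,
                                                  config$station_elevation,
                                                  1.4e-4),
                             elevation = config$station_elevation,
                             source = "reconstruction at station")
  adj <- bias_adjustment(aws_est, aws)
  rec <- pressure_series(raw$time, raw$pressure + adj,
                         elevation = config$summit_elevation,
                         source = "adjusted reconstruction")
  res$reconstruction <- rec
  res$validation <- validate_reconstruction(
    pressure_series(aws_est$time, aws_est$pressure + adj,
                    elevation = config$station_elevation), aws)
  res$climatology <- doy_climatology(rec)
  emit("reconstruction.csv", function(p) write_pressure_csv(rec, p))
  emit("validation.yaml", function(p)
    yaml::write_yaml(unclass(res$validation), p))
  emit("climatology.csv", function(p)
    utils::write.csv(as.data.frame(res$climatology), p, row.names = FALSE))

  # --- physiology ---------------------------------------------------------
  vo2 <- calibrate_vo2_model()
  climb <- calibrate_climb_model(vo2)
  notable <- c(min(rec$pressure, na.rm = TRUE),
               stats::median(rec$pressure, na.rm = TRUE),
               max(rec$pressure, na.rm = TRUE))
  res$physiology <- physio_table(notable, compare = max(notable),
                                 vo2_model = vo2, climb_model = climb)
  emit("physiology.csv", function(p)
    utils::write.csv(res$physiology, p, row.names = FALSE))

  # --- extremes -----------------------------------------------------------
  res$events <- find_lowest_events(rec, n = n_events)
  res$composite <- composite_anomalies(rec, res$events,
                                       climatology = res$climatology)
  res$waves <- wave_transit_summary(fields, res$events)
  res$correlations <- list(
    temperature = pressure_covariate_correlation(rec, fields$temperature),
    wind = pressure_covariate_correlation(rec, fields$wind)
  )
  emit("events.csv", function(p)
    utils::write.csv(as.data.frame(res$events), p, row.names = FALSE))
  emit("composite.csv", function(p)
    utils::write.csv(data.frame(lag_hours = res$composite$lag_hours,
                                mean = res$composite$mean,
                                sd = res$composite$sd), p, row.names = FALSE))
  emit("waves.yaml", function(p) yaml::write_yaml(res$waves$summary, p))

  # --- trends & sensitivities --------------------------------------------
  yr <- as.POSIXlt(rec$time, tz = "UTC")$year + 1900L
  ann <- tapply(rec$pressure, yr, mean, na.rm = TRUE)
  res$trend <- theil_sen(as.numeric(names(ann)), as.numeric(ann),
                         statistic = "annual mean")
  ens <- generate_cmip_ensemble(config)
  res$sensitivity <- list(
    mean = cmip_sensitivity(ens, "mean"),
    min = cmip_sensitivity(ens, "min"),
    max = cmip_sensitivity(ens, "max")
  )
  res$projections <- do.call(rbind, lapply(delta_T, function(dt)
    project_stat(min(rec$pressure, na.rm = TRUE),
                 res$sensitivity$min, dt, vo2_model = vo2)))
  emit("trends.yaml", function(p) yaml::write_yaml(unclass(res$trend), p))
  emit("projections.csv", function(p)
    utils::write.csv(res$projections, p, row.names = FALSE))

  # --- ascents ------------------------------------------------------------
  skip_ascents <- !is.null(catalog) && length(catalog) == 1 && is.na(catalog)
  if (skip_ascents) {
    message("ascents stage skipped: no catalog supplied")
  } else {
    if (is.null(catalog)) catalog <- generate_ascent_catalog(config, truth)
    joined <- join_pressures(catalog, rec)
    res$ascents <- list(
      catalog = joined,
      table = monthly_table(joined, rec),
      anomaly = anomaly_vs_doy(joined, res$climatology)
    )
    emit("ascent_table.csv", function(p)
      utils::write.csv(as.data.frame(res$ascents$table), p, row.names = FALSE))
  }

  emit("provenance.yaml", function(p) yaml::write_yaml(list(
    seed = config$seed,
    package_version = as.character(utils::packageVersion("thickair")),
    constants = physio_constants()[c("o2_fraction", "gamma_may", "p_may",
                                     "vo2_may", "oxygenless_threshold",
                                     "vo2_sea_level")]
  ), p))
  invisible(res)
}
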