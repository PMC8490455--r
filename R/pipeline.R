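#' Default pipeline run configuration
#'
#' Returns the fully-specified default configuration for [runPipeline()].
#' Any element can be overridden by the user's list or YAML file; unnamed
#' defaults fill the gaps.
#'
#' @return nested configuration list.
#' @export
defaultRunConfig <- function() {
  list(
    seed = 1L,
    out_dir = NULL,
    reference = list(start_year = 1991L, end_year = 1995L),
    analysis_years = 1996L,
    climate = list(ny = 2L, nx = 2L, base_mean = 18, seasonal_amplitude = 9,
                   diurnal_amplitude = 5, noise_sd = 2, mean_depression = 6,
                   heatwaves = list()),
    regions = list(nrow = 1L, ncol = 2L, n_countries = 1L),
    population = list(years = c(2000L, 2010L), base_pop = 1000,
                      concentration = 1),
    exposure = list(standard = "ISO", working_hours = 9:16,
                    quarterly_pattern = "uniform"),
    economy = list(io_density = 0.3, trade_openness = 0.2),
    elasticities = list(sigma_va = 1, sigma_arm = 2, sigma_imp = 4),
    detection = list(window_days = 15L, min_duration = 3L),
    wbdd_threshold = 26)
}

#' @noRd
merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(base[[nm]]) &&
        !is.null(names(base[[nm]]))) {
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; keys mirror [defaultRunConfig()].
#' @return configuration list with defaults filled in.
#' @export
readRunConfig <- function(path) {
  user <- yaml::read_yaml(path)
  if (!is.null(user$climate$heatwaves)) {
    user$climate$heatwaves <- lapply(user$climate$heatwaves, function(h)
      do.call(heatwaveSpec, h))
  }
  merge_config(defaultRunConfig(), user)
}

#' @noRd
validate_config <- function(cfg) {
  if (!cfg$exposure$standard %in% c("ISO", "NIOSH", "Hothaps"))
    stop("config error: standard must be ISO, NIOSH or Hothaps",
         call. = FALSE)
  if (cfg$reference$start_year > min(cfg$analysis_years))
    stop("config error: reference period must precede or contain the ",
         "analysis years", call. = FALSE)
  invisible(cfg)
}

#' Run the full heatwave-to-GDP pipeline
#'
#' Orchestrates all stages over synthetic inputs: (1) generate reference
#' and analysis-year hourly meteorology (injecting any configured hot
#' spells), population grid and region map; (2) population-weight daily
#' maximum temperatures to regions, fit calendar-day thresholds on the
#' reference period and detect heatwaves in each analysis year; (3) compute
#' hourly sun and shade WBGT, workability by workload class, WBDD severity
#' and daily heatwave-day losses; (4) annualise the losses into the
#' labour-productivity shock tau with quarterly activity weights; (5)
#' calibrate the CGE model on a generated toy economy, apply the shock and
#' solve; (6) report GDP/GVA impacts. The run is a deterministic function
#' of the configuration seed.
#'
#' @param config list (see [defaultRunConfig()]) or path to a YAML file.
#' @return a list with one entry per analysis year (`catalogue`, `wbdd`,
#'   `tau`, `impacts`, `solution`) plus shared `thresholds`, `economy`,
#'   `regions` and the `manifest`. When `config$out_dir` is set, CSV
#'   artifacts and a JSON manifest are written there.
#' @export
runPipeline <- function(config = list()) {
  if (is.character(config)) config <- readRunConfig(config)
  cfg <- validate_config(merge_config(defaultRunConfig(), config))
  seed <- as.integer(cfg$seed)

  ## stage: synthetic inputs -------------------------------------------
  ref_years <- cfg$reference$start_year:cfg$reference$end_year
  clim <- cfg$climate
  mk_config <- function(years, seed_off)
    synthClimateConfig(ny = clim$ny, nx = clim$nx, years = years,
                       base_mean = clim$base_mean,
                       seasonal_amplitude = clim$seasonal_amplitude,
                       diurnal_amplitude = clim$diurnal_amplitude,
                       noise_sd = clim$noise_sd,
                       mean_depression = clim$mean_depression,
                       seed = seed + seed_off)
  ref_field <- generateMeteo(mk_config(ref_years, 0L))
  regions <- makeGridRegions(ref_field$cells$lat, ref_field$cells$lon,
                             cfg$regions$nrow, cfg$regions$ncol,
                             cfg$regions$n_countries)
  pop <- generatePopulation(ref_field$cells$lat, ref_field$cells$lon,
                            years = cfg$population$years,
                            base_pop = cfg$population$base_pop,
                            concentration = cfg$population$concentration,
                            seed = seed + 100L)
  economy <- generateToyEconomy(toyEconomyConfig(
    n_regions = nrow(regions$regions),
    n_countries = cfg$regions$n_countries,
    io_density = cfg$economy$io_density,
    trade_openness = cfg$economy$trade_openness,
    seed = seed + 200L))
  # toy economy regions inherit the map's ids
  stopifnot(nrow(economy$regions) == nrow(regions$regions))
  economy$regions$region <- regions$regions$region
  economy$regions$country <- regions$regions$country

  ## stage: thresholds on the reference period -------------------------
  pop_year0 <- min(cfg$population$years)
  ref_tmax <- populationRegionalMean(dailyTmax(ref_field), pop, regions,
                                     pop_year0)
  names(ref_tmax)[names(ref_tmax) == "value"] <- "tmax"
  thresholds <- computeThresholds(ref_tmax,
                                  window_days = cfg$detection$window_days)

  params <- calibrateCGE(economy, cfg$elasticities)
  benchmark <- solveCGE(params)
  weights <- quarterlyWeights(regions$regions$region, economy$sectors,
                              cfg$exposure$quarterly_pattern)
  wh <- cfg$exposure$working_hours

  per_year <- list()
  for (yr in cfg$analysis_years) {
    field <- generateMeteo(mk_config(yr, yr - min(cfg$analysis_years) + 1L))
    for (hw in clim$heatwaves) field <- injectHeatwave(field, hw)

    ## detection
    tmax <- populationRegionalMean(dailyTmax(field), pop, regions, yr)
    names(tmax)[names(tmax) == "value"] <- "tmax"
    catalogue <- detectEvents(tmax, thresholds,
                              min_duration = cfg$detection$min_duration)

    ## heat stress and workability over working hours only
    sun <- wbgtField(field, "sun", hours = wh)
    shade <- wbgtField(field, "shade", hours = wh)
    stop_if_nan(sun$wbgt, "sun WBGT"); stop_if_nan(shade$wbgt, "shade WBGT")

    ## regional hourly sun WBGT for the severity index
    days <- sort(unique(sun$date))
    reg_sun_hourly <- lapply(wh, function(h) {
      sel <- sun$hour == h
      vf <- valueField(sun$date[sel], field$cells$lat, field$cells$lon,
                       sun$wbgt[sel, , drop = FALSE])
      df <- populationRegionalMean(vf, pop, regions, yr)
      df$hour <- h
      df
    })
    reg_sun_hourly <- do.call(rbind, reg_sun_hourly)
    names(reg_sun_hourly)[names(reg_sun_hourly) == "value"] <- "wbgt"
    wbdd <- computeWBDD(reg_sun_hourly, catalogue, working_hours = wh,
                        threshold = cfg$wbdd_threshold)
    catalogue <- wbdd$catalogue

    ## per-cell daily shift workability by workload class and variant,
    ## then population-weighted to regions
    hw_days <- event_days(catalogue)
    losses <- list()
    for (si in seq_len(nrow(economy$sectors))) {
      sct <- economy$sectors[si, ]
      src <- if (sct$outdoor) sun else shade
      wab <- workability(src$wbgt, sct$workload, cfg$exposure$standard)
      wab <- matrix(wab, nrow(src$wbgt), ncol(src$wbgt))
      day_idx <- match(src$date, days)
      daily <- matrix(0, length(days), ncol(wab))
      for (j in seq_len(ncol(wab)))
        daily[, j] <- tapply(wab[, j], day_idx, mean)
      vf <- valueField(days, field$cells$lat, field$cells$lon, daily)
      reg <- populationRegionalMean(vf, pop, regions, yr)
      reg$loss <- 1 - reg$value
      reg <- merge(reg, hw_days, by = c("region", "date"))
      if (nrow(reg) > 0L) {
        losses[[sct$sector]] <- data.frame(region = reg$region,
                                           sector = sct$sector,
                                           date = reg$date,
                                           loss = reg$loss)
      }
    }
    daily_losses <- if (length(losses)) do.call(rbind, losses) else NULL

    ## annual shock, CGE solve, impacts
    tau <- annualizeShock(daily_losses, weights, yr,
                          regions = regions$regions$region,
                          sectors = economy$sectors$sector)
    shocked <- applyShock(params, tau)
    solution <- solveCGE(shocked)
    impacts <- impactReport(solution, benchmark)

    per_year[[as.character(yr)]] <-
      list(catalogue = catalogue, wbdd = wbdd$region_year, tau = tau,
           impacts = impacts, solution = solution)
  }

  manifest <- list(seed = seed,
                   package_version = as.character(
                     utils::packageVersion("heatshock")),
                   analysis_years = cfg$analysis_years,
                   reference = unlist(cfg$reference),
                   standard = cfg$exposure$standard,
                   n_regions = nrow(regions$regions),
                   n_sectors = nrow(economy$sectors))
  result <- list(years = per_year, thresholds = thresholds,
                 economy = economy, regions = regions, pop = pop,
                 benchmark = benchmark, manifest = manifest)

  if (!is.null(cfg$out_dir)) writeRunArtifacts(result, cfg$out_dir)
  result
}

#' Write pipeline artifacts as CSV/JSON
#'
#' @param result return value of [runPipeline()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeRunArtifacts <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (yr in names(result$years)) {
    y <- result$years[[yr]]
    write.csv(as.data.frame(y$catalogue),
              file.path(dir, paste0("catalogue_", yr, ".csv")),
              row.names = FALSE)
    write.csv(as.data.frame(y$tau),
              file.path(dir, paste0("tau_", yr, ".csv")), row.names = FALSE)
    write.csv(y$wbdd, file.path(dir, paste0("wbdd_", yr, ".csv")),
              row.names = FALSE)
    write.csv(y$impacts$regional,
              file.path(dir, paste0("impacts_region_", yr, ".csv")),
              row.names = FALSE)
    write.csv(y$impacts$sectoral,
              file.path(dir, paste0("impacts_sector_", yr, ".csv")),
              row.names = FALSE)
  }
  write.csv(as.data.frame(result$thresholds),
            file.path(dir, "thresholds.csv"), row.names = FALSE)
  writeEconomyCSV(result$economy, file.path(dir, "economy"))
  writeRegionsGeoJSON(result$regions, file.path(dir, "regions.geojson"))
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
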