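#' Configuration for the synthetic hourly meteorology generator
#'
#' Describes a rectangular grid and the statistical model of its hourly
#' weather: a cell-specific annual mean, a seasonal cycle peaking in
#' mid-July (northern hemisphere), a diurnal cycle peaking at 15 h, daily
#' Gaussian noise shared by all hours of a day, a dew-point depression drawn
#' from a Gamma law (so dew point can never exceed air temperature), a
#' clear-sky solar sinusoid with seasonally varying day length, and
#' lognormal wind.
#'
#' @param ny,nx grid dimensions (cells); both must be >= 1.
#' @param years integer vector of calendar years to generate (contiguous).
#' @param base_mean annual-mean air temperature (degC); scalar or `ny x nx`
#'   matrix of per-cell means.
#' @param seasonal_amplitude half-range of the seasonal cycle (degC); the
#'   July minus January monthly-mean difference is about twice this value.
#' @param diurnal_amplitude half-range of the diurnal cycle (degC); >= 0.
#' @param noise_sd standard deviation of the daily noise (degC); >= 0.
#' @param mean_depression mean dew-point depression Ta - Td (degC); > 0.
#' @param depression_shape Gamma shape of the depression law; larger values
#'   concentrate humidity around the mean depression.
#' @param solar_max clear-sky noon solar irradiance at the summer solstice
#'   (W m-2).
#' @param wind_meanlog,wind_sdlog lognormal parameters of hourly wind speed
#'   (m s-1); defaults give typical speeds of 1-3 m s-1.
#' @param lat0,lon0 coordinates of the first (south-west) cell centre;
#'   cells are spaced `dlat`/`dlon` degrees apart.
#' @param dlat,dlon grid spacing in degrees.
#' @param seed integer seed; identical configs give bit-identical fields.
#' @return an object of class `synth_climate_config`.
#' @seealso [generateMeteo()], [injectHeatwave()]
#' @export
synthClimateConfig <- function(ny = 3L, nx = 3L, years = 2001L,
                               base_mean = 18, seasonal_amplitude = 9,
                               diurnal_amplitude = 5, noise_sd = 2,
                               mean_depression = 8, depression_shape = 4,
                               solar_max = 850,
                               wind_meanlog = log(2), wind_sdlog = 0.35,
                               lat0 = 40, lon0 = 0, dlat = 1, dlon = 1,
                               seed = 1L) {
  if (ny < 1L || nx < 1L)
    stop("invalid config: grid shape must be positive", call. = FALSE)
  if (length(years) < 1L)
    stop("invalid config: at least one year required", call. = FALSE)
  years <- sort(as.integer(years))
  if (length(years) > 1L && any(diff(years) != 1L))
    stop("invalid config: years must be contiguous", call. = FALSE)
  if (diurnal_amplitude < 0) stop("invalid config: diurnal_amplitude < 0",
                                  call. = FALSE)
  if (noise_sd < 0) stop("invalid config: noise_sd < 0", call. = FALSE)
  if (mean_depression <= 0) stop("invalid config: mean_depression <= 0",
                                 call. = FALSE)
  if (is.matrix(base_mean) && !all(dim(base_mean) == c(ny, nx)))
    stop("invalid config: base_mean matrix must be ny x nx", call. = FALSE)
  structure(list(ny = as.integer(ny), nx = as.integer(nx), years = years,
                 base_mean = base_mean,
                 seasonal_amplitude = seasonal_amplitude,
                 diurnal_amplitude = diurnal_amplitude, noise_sd = noise_sd,
                 mean_depression = mean_depression,
                 depression_shape = depression_shape, solar_max = solar_max,
                 wind_meanlog = wind_meanlog, wind_sdlog = wind_sdlog,
                 lat0 = lat0, lon0 = lon0, dlat = dlat, dlon = dlon,
                 seed = as.integer(seed)),
            class = "synth_climate_config")
}

# seasonal phase: mid-July peak (climatological day 196)
.seasonal_term <- function(doy, amplitude) {
  amplitude * cos(2 * pi * (doy - 196) / 365.2425)
}

#' Generate a synthetic hourly gridded meteorology field
#'
#' Produces hourly air temperature (`tas`, degC), dew-point temperature
#' (`tdps`, degC), downwelling solar radiation (`rsds`, W m-2, zero at
#' night) and wind speed (`sfcWind`, m s-1) on the configured grid, as
#' `n_hours x n_cells` matrices. Output is a deterministic function of the
#' configuration (including its seed).
#'
#' @param config a [synthClimateConfig()] object.
#' @return an object of class `hourly_meteo_field`: a list with elements
#'   `time` (POSIXct, UTC), `date`, `hour`, `cells` (data frame of cell id,
#'   row, col, lat, lon), matrices `tas`, `tdps`, `rsds`, `sfcWind`, and the
#'   generating `config`.
#' @export
generateMeteo <- function(config) {
  stopifnot(inherits(config, "synth_climate_config"))
  y0 <- config$years[1L]; y1 <- config$years[length(config$years)]
  t0 <- as.POSIXct(sprintf("%d-01-01 00:00:00", y0), tz = "UTC")
  t1 <- as.POSIXct(sprintf("%d-12-31 23:00:00", y1), tz = "UTC")
  time <- seq(t0, t1, by = "hour")
  date <- as.Date(time, tz = "UTC")
  hour <- as.POSIXlt(time, tz = "UTC")$hour
  days <- seq(as.Date(t0), as.Date(t1), by = "day")
  day_idx <- match(date, days)
  doy <- climDoy(date)

  ncell <- config$ny * config$nx
  cells <- expand.grid(row = seq_len(config$ny), col = seq_len(config$nx))
  cells <- data.frame(cell = seq_len(ncell), row = cells$row, col = cells$col,
                      lat = config$lat0 + (cells$row - 1) * config$dlat,
                      lon = config$lon0 + (cells$col - 1) * config$dlon)

  base <- if (is.matrix(config$base_mean)) {
    config$base_mean[cbind(cells$row, cells$col)]
  } else rep(config$base_mean, ncell)

  seas <- .seasonal_term(doy, config$seasonal_amplitude)
  diur <- config$diurnal_amplitude * cos(2 * pi * (hour - 15) / 24)

  nday <- length(days)
  out <- with_seed(config$seed, {
    noise <- if (config$noise_sd > 0) {
      matrix(rnorm(nday * ncell, sd = config$noise_sd), nday, ncell)
    } else matrix(0, nday, ncell)
    depr <- matrix(rgamma(nday * ncell, shape = config$depression_shape,
                          scale = config$mean_depression /
                            config$depression_shape),
                   nday, ncell)
    ws <- matrix(rlnorm(length(time) * ncell, config$wind_meanlog,
                        config$wind_sdlog), length(time), ncell)
    list(noise = noise, depr = depr, ws = ws)
  })

  tas <- outer(seas + diur, base, `+`) + out$noise[day_idx, , drop = FALSE]
  tdps <- tas - out$depr[day_idx, , drop = FALSE]

  # clear-sky sinusoid: day length 8-16 h tracking the seasonal cycle
  dl <- 12 + 4 * cos(2 * pi * (doy - 196) / 365.2425)
  sunrise <- 12 - dl / 2
  frac <- (hour + 0.5 - sunrise) / dl
  sr_prof <- ifelse(frac > 0 & frac < 1, sin(pi * frac), 0)
  sr_amp <- config$solar_max * (0.7 + 0.3 * cos(2 * pi * (doy - 172) / 365.2425))
  rsds <- matrix(pmax(0, sr_prof * sr_amp), length(time), ncell)

  structure(list(time = time, date = date, hour = hour, cells = cells,
                 tas = tas, tdps = tdps, rsds = rsds, sfcWind = out$ws,
                 config = config),
            class = "hourly_meteo_field")
}

#' @export
print.hourly_meteo_field <- function(x, ...) {
  cat("<hourly_meteo_field> ", nrow(x$cells), " cells, ",
      length(x$time), " hours (", format(min(x$date)), " .. ",
      format(max(x$date)), ")\n", sep = "")
  invisible(x)
}

#' Specify a hot spell to inject into a meteorology field
#'
#' @param start_date first day of the spell (`Date` or string).
#' @param duration length in days; >= 1.
#' @param amplitude peak temperature increment (degC); >= 0.
#' @param cells integer cell ids to perturb; `NULL` means every cell.
#' @param shape `"block"` (constant increment) or `"ramp"` (triangular
#'   profile peaking mid-spell).
#' @return an object of class `heatwave_spec`.
#' @export
heatwaveSpec <- function(start_date, duration, amplitude,
                         cells = NULL, shape = c("block", "ramp")) {
  shape <- match.arg(shape)
  duration <- as.integer(duration)
  if (duration < 1L) stop("duration must be >= 1", call. = FALSE)
  if (amplitude < 0) stop("amplitude must be >= 0", call. = FALSE)
  structure(list(start_date = as.Date(start_date), duration = duration,
                 amplitude = amplitude, cells = cells, shape = shape),
            class = "heatwave_spec")
}

#' Inject a hot spell into an hourly meteorology field
#'
#' Raises air temperature on the spell days by the amplitude profile
#' (every hour of a day gets the same increment, so daily maxima rise by
#' exactly the profile value). Dew point is left untouched: the dew-point
#' depression widens, which keeps the Td <= Ta invariant.
#'
#' @param field an `hourly_meteo_field`.
#' @param spec a [heatwaveSpec()].
#' @return the modified field.
#' @export
injectHeatwave <- function(field, spec) {
  stopifnot(inherits(field, "hourly_meteo_field"),
            inherits(spec, "heatwave_spec"))
  days <- spec$start_date + seq_len(spec$duration) - 1L
  if (min(days) < min(field$date) || max(days) > max(field$date))
    stop("heatwave spec outside the field's time span", call. = FALSE)
  prof <- switch(spec$shape,
    block = rep(spec$amplitude, spec$duration),
    ramp = {
      d <- spec$duration
      if (d == 1L) spec$amplitude
      else spec$amplitude * (1 - abs(2 * (seq_len(d) - 1) / (d - 1) - 1))
    })
  cells <- spec$cells %||% field$cells$cell
  for (i in seq_along(days)) {
    sel <- field$date == days[i]
    field$tas[sel, cells] <- field$tas[sel, cells] + prof[i]
  }
  field
}

#' Daily maximum temperature per cell
#'
#' @param field an `hourly_meteo_field`.
#' @return a `value_field`: list with `dates`, `lat`, `lon` (cell centres)
#'   and a `values` matrix of daily maxima (`n_days x n_cells`).
#' @export
dailyTmax <- function(field) {
  stopifnot(inherits(field, "hourly_meteo_field"))
  days <- sort(unique(field$date))
  idx <- match(field$date, days)
  ncell <- nrow(field$cells)
  vals <- matrix(-Inf, length(days), ncell)
  for (j in seq_len(ncell)) {
    vals[, j] <- tapply(field$tas[, j], idx, max)
  }
  structure(list(dates = days, lat = field$cells$lat, lon = field$cells$lon,
                 values = vals),
            class = "value_field")
}

#' Build a daily-values field from a matrix
#'
#' Container used to hand gridded daily quantities (Tmax, workability,
#' losses) to the population-weighting step.
#'
#' @param dates `Date` vector of length `nrow(values)`.
#' @param lat,lon cell-centre coordinates of length `ncol(values)`.
#' @param values numeric matrix, days in rows and cells in columns.
#' @return an object of class `value_field`.
#' @export
valueField <- function(dates, lat, lon, values) {
  values <- as.matrix(values)
  stopifnot(length(dates) == nrow(values), length(lat) == ncol(values),
            length(lon) == ncol(values))
  structure(list(dates = as.Date(dates), lat = lat, lon = lon,
                 values = values),
            class = "value_field")
}
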