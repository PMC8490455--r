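#' Workload classes and exposure-function parameters
#'
#' Three workload intensity classes with their metabolic rates (low 200 W,
#' moderate 300 W, high 400 W; 117 W at rest) and the two-parameter
#' logistic (alpha1, alpha2) coefficients of the Hothaps exposure function:
#' (34.64, 22.72) low, (32.93, 17.81) moderate, (30.94, 16.64) high.
#'
#' @format `workload_classes`: data frame with columns `label`, `M` (W),
#'   `alpha1`, `alpha2`. `M_REST`: the resting metabolic rate in watts.
#' @export
workload_classes <- data.frame(
  label = c("low", "moderate", "high"),
  M = c(200, 300, 400),
  alpha1 = c(34.64, 32.93, 30.94),
  alpha2 = c(22.72, 17.81, 16.64))

#' @rdname workload_classes
#' @export
M_REST <- 117

#' @noRd
metabolic_rate <- function(workload) {
  m <- workload_classes$M[match(workload, workload_classes$label)]
  if (any(is.na(m)))
    stop("unknown workload class: ",
         paste(setdiff(workload, workload_classes$label), collapse = ", "),
         call. = FALSE)
  m
}

#' Metabolic-rate-dependent WBGT exposure limit
#'
#' ISO limit: 34.9 - M/46. NIOSH limit: 56.7 - 11.5 log10(M). The limit is
#' the WBGT at which workability starts to fall below one; applying the
#' same formula to the resting rate (117 W) gives the WBGT at which work
#' stops entirely.
#'
#' @param M metabolic rate in watts; > 0.
#' @param standard `"ISO"` or `"NIOSH"`.
#' @return limit WBGT in degC.
#' @export
wbgtLim <- function(M, standard = c("ISO", "NIOSH")) {
  standard <- match.arg(standard)
  if (any(M <= 0)) stop("invalid input: M must be positive", call. = FALSE)
  switch(standard,
         ISO = 34.9 - M / 46,
         NIOSH = 56.7 - 11.5 * log10(M))
}

#' Hourly workability from WBGT
#'
#' ISO and NIOSH: a clamped linear ramp, workability =
#' max(0, min(1, (WBGT_lim,rest - WBGT) / (WBGT_lim,rest - WBGT_lim))),
#' where WBGT_lim depends on the workload's metabolic rate and
#' WBGT_lim,rest applies the same limit formula to the resting rate.
#' Hothaps: the two-parameter logistic 0.1 + 0.9 / (1 + (WBGT/alpha1)^
#' alpha2), floored at 10% (work remains possible for six minutes per hour
#' under any heat).
#'
#' @param wbgt hourly WBGT in degC (vectorised).
#' @param workload `"low"`, `"moderate"` or `"high"`.
#' @param standard `"ISO"`, `"NIOSH"` or `"Hothaps"`.
#' @return workability fraction: in \[0, 1\] for ISO/NIOSH, \[0.1, 1\] for
#'   Hothaps.
#' @export
workability <- function(wbgt, workload = "moderate",
                        standard = c("ISO", "NIOSH", "Hothaps")) {
  standard <- match.arg(standard)
  if (standard %in% c("ISO", "NIOSH")) {
    lim <- wbgtLim(metabolic_rate(workload), standard)
    lim_rest <- wbgtLim(M_REST, standard)
    pmax(0, pmin(1, (lim_rest - wbgt) / (lim_rest - lim)))
  } else {
    i <- match(workload, workload_classes$label)
    if (any(is.na(i)))
      stop("unknown workload class", call. = FALSE)
    a1 <- workload_classes$alpha1[i]; a2 <- workload_classes$alpha2[i]
    0.1 + 0.9 / (1 + (pmax(wbgt, 0) / a1)^a2)
  }
}

#' Daily workability averaged over the working shift
#'
#' Arithmetic mean of the hourly workability values over the working day,
#' read as the half-open interval 9-17 h: the eight hourly values at hours
#' 9..16.
#'
#' @param hourly data frame with columns `date`, `hour` and `workability`.
#' @param working_hours integer hours of the shift (default 9:16).
#' @return data frame with columns `date` and `workability` (daily shift
#'   mean).
#' @export
dailyShiftWorkability <- function(hourly, working_hours = 9:16) {
  stopifnot(is.data.frame(hourly),
            all(c("date", "hour", "workability") %in% names(hourly)))
  wk <- hourly[hourly$hour %in% working_hours, ]
  n <- aggregate(list(n = wk$hour), list(date = wk$date), length)
  if (any(n$n < length(working_hours)))
    stop("coverage error: missing working hours on ",
         paste(head(n$date[n$n < length(working_hours)], 3), collapse = ", "),
         call. = FALSE)
  aggregate(list(workability = wk$workability), list(date = wk$date), mean)
}

#' Population-weighted regional mean of a gridded daily field
#'
#' The climate field is regridded to the population grid by nearest
#' neighbour; each region's value is the population-weighted mean over the
#' population cells whose centres fall inside the region polygon, with the
#' population linearly interpolated to the target year. Regions with zero
#' population fall back to the unweighted mean with a warning.
#'
#' @param field a `value_field` (see [valueField()]).
#' @param pop a `population_grid`.
#' @param regions a `region_set`.
#' @param year target year for the population interpolation.
#' @return data frame with columns `date`, `region`, `value`.
#' @export
populationRegionalMean <- function(field, pop, regions, year) {
  stopifnot(inherits(field, "value_field"),
            inherits(pop, "population_grid"),
            inherits(regions, "region_set"))
  # nearest field cell for every population cell
  nn <- vapply(seq_along(pop$lat), function(i) {
    which.min((field$lat - pop$lat[i])^2 + (field$lon - pop$lon[i])^2)
  }, integer(1))
  vals <- field$values[, nn, drop = FALSE]
  w <- populationAtYear(pop, year)
  reg_of <- assignCells(pop$lat, pop$lon, regions)
  out <- lapply(regions$regions$region, function(r) {
    sel <- which(!is.na(reg_of) & reg_of == r)
    if (length(sel) == 0L)
      stop("region ", r, " contains no population cells", call. = FALSE)
    wr <- w[sel]
    if (sum(wr) <= 0) {
      warning("region ", r, " has zero population; using unweighted mean",
              call. = FALSE)
      wr <- rep(1, length(sel))
    }
    v <- as.vector(vals[, sel, drop = FALSE] %*% wr / sum(wr))
    data.frame(date = field$dates, region = r, value = v)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Uniform or seasonal quarterly activity weights
#'
#' Share of a sector's annual activity occurring in each quarter. The
#' `"uniform"` pattern gives 0.25 to every quarter; `"summer_outdoor"`
#' tilts outdoor sectors towards the third quarter (0.2, 0.3, 0.3, 0.2),
#' emulating the summer concentration of agricultural and construction
#' output.
#'
#' @param regions character vector of region ids.
#' @param sectors data frame with columns `sector` and `outdoor` (logical).
#' @param pattern `"uniform"` or `"summer_outdoor"`.
#' @return data frame with columns `region`, `sector`, `quarter`, `w`;
#'   weights sum to one within each (region, sector).
#' @export
quarterlyWeights <- function(regions, sectors,
                             pattern = c("uniform", "summer_outdoor")) {
  pattern <- match.arg(pattern)
  out <- expand.grid(region = regions, sector = sectors$sector,
                     quarter = 1:4, stringsAsFactors = FALSE)
  out$w <- 0.25
  if (pattern == "summer_outdoor") {
    outdoor <- sectors$sector[sectors$outdoor]
    sel <- out$sector %in% outdoor
    out$w[sel] <- c(0.2, 0.3, 0.3, 0.2)[out$quarter[sel]]
  }
  out[order(out$region, out$sector, out$quarter), ]
}

#' Annual-equivalent labour-productivity shock
#'
#' Aggregates daily heatwave-day productivity losses into the annual shock
#' tau applied to labour productivity: tau_rs = sum_q w_qrs * (sum of
#' weekday losses on heatwave days in quarter q) / D_q, where D_q is the
#' number of weekdays (Monday-Friday) in quarter q of the year and w_qrs is
#' the quarterly activity share. A heatwave-free year gives tau = 0.
#'
#' @param daily_losses data frame with columns `region`, `sector`, `date`
#'   and `loss` (1 - daily shift workability, on heatwave days only).
#' @param weights quarterly weights as from [quarterlyWeights()]; must sum
#'   to one within every (region, sector).
#' @param year calendar year of the shock.
#' @param regions,sectors ids to report (combinations absent from
#'   `daily_losses` get tau = 0); defaults to those present in `weights`.
#' @return an object of class `productivity_shock`: data frame with
#'   columns `region`, `sector`, `year`, `tau`.
#' @export
annualizeShock <- function(daily_losses, weights, year,
                           regions = NULL, sectors = NULL) {
  stopifnot(is.data.frame(weights),
            all(c("region", "sector", "quarter", "w") %in% names(weights)))
  sums <- aggregate(list(w = weights$w),
                    list(region = weights$region, sector = weights$sector),
                    sum)
  if (any(abs(sums$w - 1) > 1e-8))
    stop("invalid input: quarterly weights must sum to 1 per region-sector",
         call. = FALSE)
  regions <- regions %||% unique(weights$region)
  sectors <- sectors %||% unique(weights$sector)
  all_days <- seq(as.Date(sprintf("%d-01-01", year)),
                  as.Date(sprintf("%d-12-31", year)), by = "day")
  wd <- all_days[is_weekday(all_days)]
  D_q <- tabulate(quarter_of(wd), nbins = 4L)
  grid <- expand.grid(region = regions, sector = sectors,
                      stringsAsFactors = FALSE)
  grid$year <- as.integer(year)
  grid$tau <- 0
  if (!is.null(daily_losses) && nrow(daily_losses) > 0L) {
    stopifnot(all(c("region", "sector", "date", "loss") %in%
                    names(daily_losses)))
    dl <- daily_losses
    dl$date <- as.Date(dl$date)
    dl <- dl[is_weekday(dl$date) &
               as.integer(format(dl$date, "%Y")) == year, ]
    if (nrow(dl) > 0L) {
      dl$quarter <- quarter_of(dl$date)
      agg <- aggregate(list(S = dl$loss),
                       list(region = dl$region, sector = dl$sector,
                            quarter = dl$quarter), sum)
      agg <- merge(agg, weights, by = c("region", "sector", "quarter"))
      agg$contrib <- agg$w * agg$S / D_q[agg$quarter]
      tau <- aggregate(list(tau = agg$contrib),
                       list(region = agg$region, sector = agg$sector), sum)
      m <- match(paste(grid$region, grid$sector),
                 paste(tau$region, tau$sector))
      grid$tau[!is.na(m)] <- tau$tau[m[!is.na(m)]]
    }
  }
  if (any(grid$tau < 0 | grid$tau >= 1))
    stop("invalid shock: tau outside [0, 1)", call. = FALSE)
  structure(grid, class = c("productivity_shock", "data.frame"))
}
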