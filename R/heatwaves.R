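#' Calendar-day 90th-percentile temperature thresholds
#'
#' ETCCDI-style TX90p thresholds: for every calendar day (1..365, leap days
#' mapped onto 28 February), pool the daily maximum temperatures falling in
#' a centred window of `window_days` days across all reference years, and
#' take the `prob` quantile with the linear-interpolation (type 7)
#' estimator. The window wraps around the turn of the year.
#'
#' @param reference data frame with columns `region`, `date` (Date) and
#'   `tmax` (degC), covering at least two full calendar years of contiguous
#'   daily dates per region.
#' @param window_days odd window width in days (default 15).
#' @param prob percentile (default 0.9).
#' @return an object of class `threshold_series`: data frame with columns
#'   `region`, `doy` (1..365) and `threshold` (degC); the window width,
#'   probability and reference span are stored as attributes.
#' @export
computeThresholds <- function(reference, window_days = 15L, prob = 0.9) {
  stopifnot(is.data.frame(reference),
            all(c("region", "date", "tmax") %in% names(reference)))
  window_days <- as.integer(window_days)
  if (window_days %% 2L == 0L)
    stop("window_days must be odd", call. = FALSE)
  reference$date <- as.Date(reference$date)
  yrs <- unique(as.integer(format(reference$date, "%Y")))
  if (length(yrs) < 2L)
    stop("insufficient data: reference must span at least 2 full years",
         call. = FALSE)
  half <- window_days %/% 2L
  res <- lapply(split(reference, reference$region), function(df) {
    if (any(diff(sort(df$date)) != 1))
      stop("insufficient data: reference dates must be contiguous daily",
           call. = FALSE)
    doy <- climDoy(df$date)
    by_doy <- split(df$tmax, factor(doy, levels = 1:365))
    thr <- vapply(1:365, function(d) {
      win <- ((d - half - 1L):(d + half - 1L)) %% 365L + 1L
      quantile(unlist(by_doy[win], use.names = FALSE), prob,
               type = 7, names = FALSE)
    }, numeric(1))
    data.frame(region = df$region[1L], doy = 1:365, threshold = thr)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  structure(out, class = c("threshold_series", "data.frame"),
            window_days = window_days, prob = prob,
            reference_years = range(yrs))
}

#' Detect heatwave events with the TX90p rule
#'
#' A heatwave is a maximal run of at least `min_duration` consecutive days
#' on which the daily maximum temperature exceeds its calendar-day
#' threshold. Runs are not merged across non-exceedance gap days. Events
#' starting in June-August carry a summer flag.
#'
#' @param series data frame with columns `region`, `date`, `tmax`;
#'   contiguous daily dates per region.
#' @param thresholds a `threshold_series` covering every region in
#'   `series`.
#' @param min_duration minimum run length in days (default 3).
#' @return an object of class `heatwave_catalogue`: data frame with columns
#'   `region`, `start` (Date), `duration` (days), `year` (of the start),
#'   `summer` (logical) and `wbdd` (NA until [computeWBDD()] fills it),
#'   sorted by region and start date.
#' @export
detectEvents <- function(series, thresholds, min_duration = 3L) {
  stopifnot(is.data.frame(series),
            all(c("region", "date", "tmax") %in% names(series)),
            inherits(thresholds, "threshold_series"))
  series$date <- as.Date(series$date)
  min_duration <- as.integer(min_duration)
  events <- lapply(split(series, series$region), function(df) {
    df <- df[order(df$date), ]
    if (any(diff(df$date) != 1))
      stop("alignment error: series dates must be contiguous daily",
           call. = FALSE)
    thr <- thresholds[thresholds$region == df$region[1L], ]
    if (nrow(thr) == 0L)
      stop("alignment error: no thresholds for region ", df$region[1L],
           call. = FALSE)
    t_by_doy <- thr$threshold[match(climDoy(df$date), thr$doy)]
    if (any(is.na(t_by_doy)))
      stop("alignment error: thresholds do not cover all calendar days",
           call. = FALSE)
    exceed <- df$tmax > t_by_doy
    r <- rle(exceed)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= min_duration
    if (!any(keep)) return(NULL)
    data.frame(region = df$region[1L], start = df$date[starts[keep]],
               duration = r$lengths[keep])
  })
  events <- do.call(rbind, events[!vapply(events, is.null, logical(1))])
  if (is.null(events)) {
    events <- data.frame(region = character(0),
                         start = as.Date(character(0)),
                         duration = integer(0))
  }
  events <- events[order(events$region, events$start), , drop = FALSE]
  events$year <- as.integer(format(events$start, "%Y"))
  events$summer <- as.integer(format(events$start, "%m")) %in% 6:8
  events$wbdd <- rep(NA_real_, nrow(events))
  rownames(events) <- NULL
  structure(events, class = c("heatwave_catalogue", "data.frame"),
            min_duration = min_duration)
}

#' @noRd
event_days <- function(catalogue) {
  if (nrow(catalogue) == 0L)
    return(data.frame(region = character(0), date = as.Date(character(0)),
                      event = integer(0)))
  out <- lapply(seq_len(nrow(catalogue)), function(i) {
    data.frame(region = catalogue$region[i],
               date = catalogue$start[i] + 0:(catalogue$duration[i] - 1L),
               event = i)
  })
  do.call(rbind, out)
}

#' Catalogue summary statistics
#'
#' Per-year event counts, mean and median durations split by summer
#' (June-August start) versus non-summer events, and the daily share of
#' regions with an active heatwave.
#'
#' @param catalogue a `heatwave_catalogue`.
#' @param regions character vector of all region ids under study (used as
#'   the denominator of the area-affected share).
#' @param dates optional `Date` vector over which to evaluate the
#'   area-affected series; defaults to the days spanned by the catalogue.
#' @return a list with data frames `events_per_year` (`year`, `n`),
#'   `duration_by_season` (`season`, `n`, `mean_duration`,
#'   `median_duration`) and `area_affected` (`date`, `pct_regions`).
#' @export
catalogueStats <- function(catalogue, regions, dates = NULL) {
  stopifnot(inherits(catalogue, "heatwave_catalogue"), length(regions) > 0)
  if (nrow(catalogue) == 0L) {
    if (is.null(dates)) dates <- as.Date(character(0))
    return(list(
      events_per_year = data.frame(year = integer(0), n = integer(0)),
      duration_by_season = data.frame(season = character(0), n = integer(0),
                                      mean_duration = numeric(0),
                                      median_duration = numeric(0)),
      area_affected = data.frame(date = dates,
                                 pct_regions = rep(0, length(dates)))))
  }
  epy <- aggregate(list(n = catalogue$duration),
                   list(year = catalogue$year), length)
  season <- ifelse(catalogue$summer, "summer", "non-summer")
  dbs <- do.call(rbind, lapply(split(catalogue$duration, season), function(d)
    data.frame(n = length(d), mean_duration = mean(d),
               median_duration = median(d))))
  dbs <- data.frame(season = rownames(dbs), dbs, row.names = NULL)
  ed <- event_days(catalogue)
  if (is.null(dates)) dates <- seq(min(ed$date), max(ed$date), by = "day")
  active <- aggregate(list(n_regions = ed$region),
                      list(date = ed$date),
                      function(r) length(unique(r)))
  pct <- rep(0, length(dates))
  m <- match(active$date, dates)
  pct[m[!is.na(m)]] <- 100 * active$n_regions[!is.na(m)] / length(regions)
  list(events_per_year = epy, duration_by_season = dbs,
       area_affected = data.frame(date = dates, pct_regions = pct))
}

#' Wet Bulb Degree-Day severity of catalogued heatwaves
#'
#' For every heatwave day, the mean over working hours of the WBGT
#' exceedance above the threshold (max(0, WBGT - 26)) is accumulated;
#' summing over an event's days gives its severity in degC day, and summing
#' events gives the region-year totals. Hours outside heatwave days never
#' contribute.
#'
#' @param wbgt data frame of hourly regional sun-variant WBGT with columns
#'   `region`, `date`, `hour`, `wbgt`; must cover all working hours of
#'   every catalogued event day.
#' @param catalogue a `heatwave_catalogue`.
#' @param working_hours integer hours of the working day (default 9..16,
#'   the half-open 9-17 h shift).
#' @param threshold exceedance threshold in degC (default 26).
#' @return a list with `catalogue` (the input with its `wbdd` severity
#'   column filled) and `region_year` (data frame `region`, `year`,
#'   `wbdd`).
#' @export
computeWBDD <- function(wbgt, catalogue, working_hours = 9:16,
                        threshold = 26) {
  stopifnot(is.data.frame(wbgt),
            all(c("region", "date", "hour", "wbgt") %in% names(wbgt)),
            inherits(catalogue, "heatwave_catalogue"))
  wbgt$date <- as.Date(wbgt$date)
  wk <- wbgt[wbgt$hour %in% working_hours, ]
  key <- paste(wk$region, wk$date)
  exc <- split(pmax(0, wk$wbgt - threshold), key)
  n_h <- lengths(exc)
  if (nrow(catalogue) > 0L) {
    catalogue$wbdd <- vapply(seq_len(nrow(catalogue)), function(i) {
      days <- catalogue$start[i] + 0:(catalogue$duration[i] - 1L)
      ks <- paste(catalogue$region[i], days)
      if (!all(ks %in% names(exc)) ||
          any(n_h[ks] < length(working_hours)))
        stop("coverage error: WBGT series missing working hours for event ",
             "days in region ", catalogue$region[i], call. = FALSE)
      sum(vapply(exc[ks], mean, numeric(1)))
    }, numeric(1))
  }
  ry <- if (nrow(catalogue) == 0L) {
    data.frame(region = character(0), year = integer(0), wbdd = numeric(0))
  } else {
    aggregate(list(wbdd = catalogue$wbdd),
              list(region = catalogue$region, year = catalogue$year), sum)
  }
  list(catalogue = catalogue, region_year = ry)
}
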