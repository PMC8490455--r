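#' Fit an empirical quantile-mapping bias correction
#'
#' Pairs the empirical quantiles of a modelled daily series with those of
#' an observed series over a calibration period, optionally in monthly
#' windows. Applying the fitted map to the calibration model series
#' reproduces the observed quantiles at the fitted points.
#'
#' @param obs,model data frames with columns `date` and `value`, covering
#'   the calibration period.
#' @param n_quantiles number of fitted quantiles (default 99, i.e. the
#'   percentiles 1..99).
#' @param window `"month"` for twelve monthly mappings or `"none"` for a
#'   single annual mapping.
#' @param calibration optional two-element `Date` vector restricting both
#'   series to a calibration period before fitting.
#' @return an object of class `qm_model`: per window, the paired
#'   non-decreasing quantile vectors `q_model` and `q_obs` and the
#'   probabilities.
#' @export
fitQM <- function(obs, model, n_quantiles = 99L,
                  window = c("month", "none"), calibration = NULL) {
  window <- match.arg(window)
  stopifnot(is.data.frame(obs), is.data.frame(model),
            all(c("date", "value") %in% names(obs)),
            all(c("date", "value") %in% names(model)))
  obs$date <- as.Date(obs$date); model$date <- as.Date(model$date)
  if (!is.null(calibration)) {
    calibration <- as.Date(calibration)
    obs <- obs[obs$date >= calibration[1L] & obs$date <= calibration[2L], ]
    model <- model[model$date >= calibration[1L] &
                     model$date <= calibration[2L], ]
  }
  if (nrow(obs) == 0L || nrow(model) == 0L)
    stop("insufficient data: empty calibration overlap", call. = FALSE)
  probs <- seq_len(n_quantiles) / (n_quantiles + 1)
  win_of <- function(d) {
    if (window == "month") format(d, "%m") else rep("all", length(d))
  }
  wins <- sort(unique(c(win_of(obs$date), win_of(model$date))))
  maps <- lapply(wins, function(w) {
    o <- obs$value[win_of(obs$date) == w]
    m <- model$value[win_of(model$date) == w]
    if (length(o) == 0L || length(m) == 0L)
      stop("insufficient data: window ", w, " empty in one series",
           call. = FALSE)
    list(q_model = quantile(m, probs, type = 7, names = FALSE),
         q_obs = quantile(o, probs, type = 7, names = FALSE))
  })
  names(maps) <- wins
  structure(list(maps = maps, probs = probs, window = window,
                 extrapolation = "constant-delta"),
            class = "qm_model")
}

#' Apply a fitted quantile-mapping correction
#'
#' Values inside the calibrated range are mapped by piecewise-linear
#' interpolation between the fitted (model, observed) quantile pairs.
#' Values beyond the range receive the boundary correction: the constant
#' delta `q_obs - q_model` of the nearest fitted quantile is added.
#'
#' @param qm a `qm_model` from [fitQM()].
#' @param series data frame with columns `date` and `value`.
#' @return the series with corrected `value`.
#' @export
applyQM <- function(qm, series) {
  stopifnot(inherits(qm, "qm_model"), is.data.frame(series),
            all(c("date", "value") %in% names(series)))
  series$date <- as.Date(series$date)
  win <- if (qm$window == "month") format(series$date, "%m")
         else rep("all", nrow(series))
  out <- series$value
  for (w in unique(win)) {
    map <- qm$maps[[w]]
    if (is.null(map))
      stop("lookup error: no fitted mapping for window ", w, call. = FALSE)
    sel <- win == w
    x <- series$value[sel]
    qa <- map$q_model; qo <- map$q_obs
    if (length(unique(qa)) < 2L) {
      # degenerate map (constant model series): plain delta correction
      y <- x + (qo[1L] - qa[1L])
    } else {
      y <- approx(qa, qo, x, ties = "ordered", rule = 1)$y
      lo <- x < qa[1L]; hi <- x > qa[length(qa)]
      y[lo] <- x[lo] + (qo[1L] - qa[1L])
      y[hi] <- x[hi] + (qo[length(qo)] - qa[length(qa)])
    }
    out[sel] <- y
  }
  series$value <- out
  series
}

#' Serialise a quantile-mapping model to JSON
#' @param qm a `qm_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
qmToJSON <- function(qm, path) {
  stopifnot(inherits(qm, "qm_model"))
  jsonlite::write_json(unclass(qm), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a quantile-mapping model from JSON
#' @param path file written by [qmToJSON()].
#' @return a `qm_model`.
#' @export
qmFromJSON <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$maps <- lapply(x$maps, function(m)
    list(q_model = as.numeric(m$q_model), q_obs = as.numeric(m$q_obs)))
  structure(x, class = "qm_model")
}
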