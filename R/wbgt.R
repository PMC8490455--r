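#' Constants of the WBGT energy-balance formulation
#'
#' Coefficient set used by [wbgtSun()] and [wbgtShade()]. Saturation vapour
#' pressure follows the WMO Magnus form e_s(T) = 6.112 exp(17.62 T /
#' (243.12 + T)) hPa; the psychrometer constant is 0.000662 K-1 at standard
#' pressure (1013.25 hPa). The natural wet-bulb temperature solves the wick
#' energy balance e_s(Tnwb) + gamma Tnwb = e_a + gamma (Ta + G), where the
#' radiative gain G = c_rad SR / WS^0.56 converts absorbed short-wave
#' radiation into an equivalent dry-bulb increment (zero in the shade).
#' Globe temperature solves the black-globe radiation balance
#' eps sigma (Tg_K^4 - Ta_K^4) + h(WS) (Tg - Ta) = alpha_eff SR with
#' h(WS) = c_conv WS^0.6. The effective solar absorptivity alpha_eff folds
#' the sphere's projected-to-total area ratio (1/4) into the globe
#' absorptivity.
#'
#' @format a named list of numeric coefficients.
#' @export
wbgt_constants <- list(
  magnus_a    = 6.112,    # hPa
  magnus_b    = 17.62,
  magnus_c    = 243.12,   # degC
  pressure    = 1013.25,  # hPa
  psychro     = 0.000662, # K-1 (gamma = psychro * pressure, hPa K-1)
  wick_rad    = 0.010,    # degC per W m-2 at 1 m s-1
  wick_wind_exp = 0.56,
  globe_conv  = 6.3,      # W m-2 K-1 at 1 m s-1 (150 mm globe)
  globe_wind_exp = 0.6,
  globe_alpha_eff = 0.25,
  globe_emiss = 0.95,
  stefan_boltzmann = 5.670374e-8, # W m-2 K-4
  min_wind    = 0.13,     # m s-1, stall speed of the convective correlations
  shade_wind  = 1.0,      # m s-1, fixed wind of the shade variant
  tol         = 1e-4,     # degC, iteration tolerance
  max_iter    = 100L
)

#' @noRd
e_sat <- function(t) {
  k <- wbgt_constants
  k$magnus_a * exp(k$magnus_b * t / (k$magnus_c + t))
}

#' @noRd
de_sat <- function(t) {
  k <- wbgt_constants
  e_sat(t) * k$magnus_b * k$magnus_c / (k$magnus_c + t)^2
}

# Natural wet-bulb temperature from the wick balance; `gain` is the
# radiative equivalent dry-bulb increment in degC (0 for shade).
# Newton iteration on the monotone residual, tolerance wbgt_constants$tol.
#' @noRd
natural_wet_bulb <- function(ta, td, gain = 0) {
  k <- wbgt_constants
  gamma <- k$psychro * k$pressure
  ea <- e_sat(td)
  rhs <- ea + gamma * (ta + gain)
  tw <- td + (ta - td) * 0.3  # start between dew point and dry bulb
  for (it in seq_len(k$max_iter)) {
    f <- e_sat(tw) + gamma * tw - rhs
    step <- f / (de_sat(tw) + gamma)
    tw <- tw - step
    if (max(abs(step)) < k$tol) return(tw)
  }
  stop("natural wet-bulb iteration did not converge (max |step| = ",
       signif(max(abs(step)), 3), " degC)", call. = FALSE)
}

# Globe temperature from the radiation balance; Newton on the monotone
# residual.
#' @noRd
globe_temperature <- function(ta, sr, ws) {
  k <- wbgt_constants
  ws <- pmax(ws, k$min_wind)
  h <- k$globe_conv * ws^k$globe_wind_exp
  es4 <- k$globe_emiss * k$stefan_boltzmann
  ta_k <- ta + 273.15
  tg <- ta + k$globe_alpha_eff * sr / h  # radiation-free linear guess
  for (it in seq_len(k$max_iter)) {
    tg_k <- tg + 273.15
    f <- es4 * (tg_k^4 - ta_k^4) + h * (tg - ta) - k$globe_alpha_eff * sr
    step <- f / (4 * es4 * tg_k^3 + h)
    tg <- tg - step
    if (max(abs(step)) < k$tol) return(tg)
  }
  stop("globe-temperature iteration did not converge", call. = FALSE)
}

#' @noRd
check_td_ta <- function(ta, td) {
  if (any(td > ta + 1e-9))
    stop("invalid input: dew point exceeds air temperature", call. = FALSE)
}

#' Outdoor (sun) Wet Bulb Globe Temperature
#'
#' WBGT_sun = 0.7 Tnwb + 0.2 Tg + 0.1 Ta, with the natural wet-bulb and
#' globe temperatures obtained from the energy balances documented in
#' [wbgt_constants]. All arguments are vectorised and recycled.
#'
#' @param ta air temperature (degC).
#' @param td dew-point temperature (degC); must not exceed `ta`.
#' @param sr downwelling solar radiation (W m-2); >= 0.
#' @param ws wind speed (m s-1); >= 0 (floored at the correlations' stall
#'   speed).
#' @return WBGT in degC.
#' @export
wbgtSun <- function(ta, td, sr, ws) {
  n <- max(length(ta), length(td), length(sr), length(ws))
  ta <- rep_len(ta, n); td <- rep_len(td, n)
  sr <- rep_len(sr, n); ws <- rep_len(ws, n)
  check_td_ta(ta, td)
  if (any(sr < 0)) stop("invalid input: negative solar radiation",
                        call. = FALSE)
  if (any(ws < 0)) stop("invalid input: negative wind speed", call. = FALSE)
  k <- wbgt_constants
  gain <- k$wick_rad * sr / pmax(ws, k$min_wind)^k$wick_wind_exp
  tnwb <- natural_wet_bulb(ta, td, gain)
  tg <- globe_temperature(ta, sr, ws)
  0.7 * tnwb + 0.2 * tg + 0.1 * ta
}

#' Indoor (shade) Wet Bulb Globe Temperature
#'
#' WBGT_shade = 0.7 Tnwb + 0.3 Ta, with the natural wet-bulb temperature
#' computed without radiant load at a fixed wind speed of 1 m s-1 (slow
#' walk). Requires only air and dew-point temperature.
#'
#' @param ta air temperature (degC).
#' @param td dew-point temperature (degC); must not exceed `ta`.
#' @return WBGT in degC.
#' @export
wbgtShade <- function(ta, td) {
  n <- max(length(ta), length(td))
  ta <- rep_len(ta, n); td <- rep_len(td, n)
  check_td_ta(ta, td)
  tnwb <- natural_wet_bulb(ta, td, gain = 0)
  0.7 * tnwb + 0.3 * ta
}

#' Hourly WBGT over a meteorology field
#'
#' Applies [wbgtSun()] or [wbgtShade()] to every hour and cell of an
#' `hourly_meteo_field`, optionally restricted to a subset of hours of the
#' day.
#'
#' @param field an `hourly_meteo_field`.
#' @param variant `"sun"` or `"shade"`.
#' @param hours integer hours of day to compute (default all); other rows
#'   are dropped from the result.
#' @return a list with `time`, `date`, `hour` (possibly subset) and a
#'   `wbgt` matrix (`n_hours_kept x n_cells`) carrying the `variant` as an
#'   attribute.
#' @export
wbgtField <- function(field, variant = c("sun", "shade"), hours = NULL) {
  stopifnot(inherits(field, "hourly_meteo_field"))
  variant <- match.arg(variant)
  keep <- if (is.null(hours)) rep(TRUE, length(field$hour))
          else field$hour %in% hours
  ta <- field$tas[keep, , drop = FALSE]
  td <- field$tdps[keep, , drop = FALSE]
  w <- if (variant == "sun") {
    sr <- field$rsds[keep, , drop = FALSE]
    ws <- field$sfcWind[keep, , drop = FALSE]
    matrix(wbgtSun(as.vector(ta), as.vector(td), as.vector(sr),
                   as.vector(ws)), nrow(ta), ncol(ta))
  } else {
    matrix(wbgtShade(as.vector(ta), as.vector(td)), nrow(ta), ncol(ta))
  }
  attr(w, "variant") <- variant
  list(time = field$time[keep], date = field$date[keep],
       hour = field$hour[keep], wbgt = w)
}

#' Approximate hourly WBGT from daily statistics (4+4+4 scheme)
#'
#' Assigns the daily maximum WBGT to the hottest part of the day (12-16 h),
#' the daily mean to the early morning (8-10 h) and early evening
#' (18-20 h), and the average of mean and maximum to the shoulders (10-12 h
#' and 16-18 h). Hours outside 8-20 h are set to the daily mean, giving a
#' full 24-hour profile.
#'
#' @param daily_mean daily mean WBGT (degC).
#' @param daily_max daily maximum WBGT (degC); must be >= `daily_mean`.
#' @return if the inputs are scalars, a named numeric vector of 24 hourly
#'   values (names "0".."23"); for vector inputs an `n_days x 24` matrix.
#' @export
approxHourly444 <- function(daily_mean, daily_max) {
  n <- max(length(daily_mean), length(daily_max))
  daily_mean <- rep_len(daily_mean, n); daily_max <- rep_len(daily_max, n)
  if (any(daily_max < daily_mean - 1e-9))
    stop("invalid input: daily maximum below daily mean", call. = FALSE)
  mid <- (daily_mean + daily_max) / 2
  hours <- 0:23
  w_max <- hours %in% 12:15
  w_mid <- hours %in% c(10, 11, 16, 17)
  out <- matrix(rep(daily_mean, each = 24), n, 24, byrow = TRUE)
  out[, w_max] <- daily_max
  out[, w_mid] <- mid
  colnames(out) <- as.character(hours)
  if (n == 1L) out[1L, ] else out
}
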