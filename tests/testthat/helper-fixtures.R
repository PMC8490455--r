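# Shared fixtures and independent oracles used across the suite.

# daily date sequence covering whole calendar years
year_days <- function(y0, y1 = y0) {
  seq(as.Date(sprintf("%d-01-01", y0)), as.Date(sprintf("%d-12-31", y1)),
      by = "day")
}

# Brute-force run-length heatwave oracle: maximal runs of >= min_dur
# consecutive exceedance days, scanned by hand.
brute_force_events <- function(dates, exceed, min_dur = 3L) {
  out <- NULL
  i <- 1L; n <- length(exceed)
  while (i <= n) {
    if (exceed[i]) {
      j <- i
      while (j < n && exceed[j + 1L]) j <- j + 1L
      if (j - i + 1L >= min_dur)
        out <- rbind(out, data.frame(start = dates[i],
                                     duration = j - i + 1L))
      i <- j + 1L
    } else i <- i + 1L
  }
  out
}

# Independent WBGT oracle: solves the same energy balances with
# stats::uniroot bracketing instead of the package's Newton iteration.
oracle_wbgt_sun <- function(ta, td, sr, ws) {
  k <- heatshock::wbgt_constants
  gamma <- k$psychro * k$pressure
  es <- function(t) k$magnus_a * exp(k$magnus_b * t / (k$magnus_c + t))
  gain <- k$wick_rad * sr / max(ws, k$min_wind)^k$wick_wind_exp
  rhs <- es(td) + gamma * (ta + gain)
  tnwb <- uniroot(function(t) es(t) + gamma * t - rhs,
                  c(-80, 150), tol = 1e-10)$root
  h <- k$globe_conv * max(ws, k$min_wind)^k$globe_wind_exp
  es4 <- k$globe_emiss * k$stefan_boltzmann
  tg <- uniroot(function(t) es4 * ((t + 273.15)^4 - (ta + 273.15)^4) +
                  h * (t - ta) - k$globe_alpha_eff * sr,
                c(ta - 1, ta + 120), tol = 1e-10)$root
  0.7 * tnwb + 0.2 * tg + 0.1 * ta
}

oracle_wbgt_shade <- function(ta, td) {
  k <- heatshock::wbgt_constants
  gamma <- k$psychro * k$pressure
  es <- function(t) k$magnus_a * exp(k$magnus_b * t / (k$magnus_c + t))
  rhs <- es(td) + gamma * ta
  tnwb <- uniroot(function(t) es(t) + gamma * t - rhs,
                  c(-80, 150), tol = 1e-10)$root
  0.7 * tnwb + 0.3 * ta
}

# quiet two-region two-sector autarkic or trading toy economy
small_economy <- function(n_regions = 2L, trade = 0.2, io = 0.3,
                          n_countries = 1L, seed = 11L) {
  generateToyEconomy(toyEconomyConfig(
    n_regions = n_regions, n_countries = n_countries,
    io_density = io, trade_openness = trade, seed = seed))
}
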