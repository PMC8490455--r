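#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Climatological day-of-year index
#'
#' Maps dates to a 1..365 calendar-day index. February 29 is assigned the
#' index of February 28, so leap days share the climatological threshold of
#' the preceding day.
#'
#' @param dates a `Date` vector.
#' @return integer vector in 1..365.
#' @export
climDoy <- function(dates) {
  dates <- as.Date(dates)
  mo <- as.integer(format(dates, "%m"))
  dy <- as.integer(format(dates, "%d"))
  # day-of-year in a fixed non-leap year (2001)
  cum <- c(0L, cumsum(c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L)))
  dy2 <- ifelse(mo == 2L & dy == 29L, 28L, dy)
  cum[mo] + dy2
}

#' @noRd
is_weekday <- function(dates) {
  wd <- as.POSIXlt(as.Date(dates))$wday
  wd >= 1L & wd <= 5L
}

#' @noRd
quarter_of <- function(dates) {
  (as.integer(format(as.Date(dates), "%m")) - 1L) %/% 3L + 1L
}

# Even-odd ray-casting point-in-polygon test. `poly` is a two-column matrix
# of vertex coordinates (closed or open ring). Points on edges count as in.
#' @noRd
point_in_polygon <- function(px, py, poly) {
  nx <- poly[, 1L]; ny <- poly[, 2L]
  n <- length(nx)
  if (nx[1L] == nx[n] && ny[1L] == ny[n]) {
    nx <- nx[-n]; ny <- ny[-n]; n <- n - 1L
  }
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    cross <- ((ny[i] > py) != (ny[j] > py)) &
      (px < (nx[j] - nx[i]) * (py - ny[i]) / (ny[j] - ny[i]) + nx[i])
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

# Run body with a temporary RNG state seeded from `seed`; the caller's
# .Random.seed is restored on exit so generators are pure in their seed.
#' @noRd
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  code
}

#' @noRd
stop_if_nan <- function(x, what) {
  if (any(!is.finite(unlist(x, use.names = FALSE))))
    stop("non-finite values in ", what, call. = FALSE)
  invisible(x)
}
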