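test_that("thresholds of a constant series equal the constant for every calendar day", {
  ref <- data.frame(region = "A", date = year_days(1991, 1994), tmax = 20)
  thr <- computeThresholds(ref)
  expect_equal(nrow(thr), 365L)
  expect_true(all(thr$threshold == 20))
  # window width is irrelevant on a constant series
  thr1 <- computeThresholds(ref, window_days = 1L)
  expect_equal(thr1$threshold, thr$threshold)
})

test_that("the percentile estimator interpolates order statistics (type 7)", {
  # 30 reference years; every day of year y carries the value y, so any
  # pooled window holds the integers 1..30 and P90 = 27.1
  dates <- year_days(1981, 2010)
  ref <- data.frame(region = "A", date = dates,
                    tmax = as.integer(format(dates, "%Y")) - 1980L)
  thr <- computeThresholds(ref, window_days = 1L)
  expect_equal(thr$threshold[thr$doy != 59],
               rep(quantile(1:30, 0.9, type = 7, names = FALSE), 364))
  expect_equal(thr$threshold[1], 27.1)
  # calendar day 59 also pools the folded Feb 29 values of leap years
  leap_extra <- seq(1984, 2010, by = 4) - 1980
  expect_equal(thr$threshold[thr$doy == 59],
               quantile(c(1:30, leap_extra), 0.9, type = 7, names = FALSE))
})

test_that("threshold preconditions are enforced", {
  ref <- data.frame(region = "A", date = year_days(1991), tmax = 20)
  expect_error(computeThresholds(ref), "2 full years")
  ref2 <- data.frame(region = "A", date = year_days(1991, 1992), tmax = 20)
  expect_error(computeThresholds(ref2, window_days = 4L), "odd")
})

test_that("run-length detection keeps only maximal runs of at least three days", {
  thr <- computeThresholds(data.frame(region = "A",
                                      date = year_days(1991, 1992),
                                      tmax = 20))
  dates <- year_days(1995)
  tm <- rep(15, 365)
  tm[10:14] <- 25        # 5-day event
  tm[100:101] <- 25      # 2-day run: discarded
  tm[150:152] <- 25      # 3-day event
  tm[200:203] <- 25      # 4-day event
  cat <- detectEvents(data.frame(region = "A", date = dates, tmax = tm), thr)
  expect_equal(nrow(cat), 3L)
  expect_equal(cat$start, dates[c(10, 150, 200)])
  expect_equal(cat$duration, c(5L, 3L, 4L))
  expect_equal(cat$summer, c(FALSE, FALSE, TRUE))
})

test_that("detector agrees with a brute-force run-length oracle on random series", {
  thr <- computeThresholds(data.frame(region = "A",
                                      date = year_days(1991, 1992),
                                      tmax = 20))
  set.seed(42)
  dates <- year_days(1995)
  for (rep in 1:20) {
    tm <- 20 + rnorm(365, 0, 1.2)
    cat <- detectEvents(data.frame(region = "A", date = dates, tmax = tm),
                        thr)
    oracle <- brute_force_events(dates, tm > 20)
    if (is.null(oracle)) {
      expect_equal(nrow(cat), 0L)
    } else {
      expect_equal(cat$start, oracle$start)
      expect_equal(cat$duration, oracle$duration)
    }
  }
})

test_that("injected heatwaves are recovered with exact start and duration", {
  # constant climatology: thresholds equal the daily maximum everywhere, so
  # only injected days exceed (strict inequality) and recovery is exact
  cfg <- synthClimateConfig(ny = 1, nx = 2, years = 1991:1992,
                            base_mean = 20, seasonal_amplitude = 0,
                            noise_sd = 0, seed = 1)
  ref <- generateMeteo(cfg)
  yr <- generateMeteo(synthClimateConfig(ny = 1, nx = 2, years = 1995,
                                         base_mean = 20,
                                         seasonal_amplitude = 0,
                                         noise_sd = 0, seed = 2))
  yr <- injectHeatwave(yr, heatwaveSpec("1995-06-10", 4, 10))
  yr <- injectHeatwave(yr, heatwaveSpec("1995-08-01", 6, 10))
  to_series <- function(f) {
    tm <- dailyTmax(f)
    data.frame(region = "A", date = tm$dates, tmax = tm$values[, 1])
  }
  thr <- computeThresholds(to_series(ref))
  cat <- detectEvents(to_series(yr), thr)
  expect_equal(nrow(cat), 2L)
  expect_equal(cat$start, as.Date(c("1995-06-10", "1995-08-01")))
  expect_equal(cat$duration, c(4L, 6L))
})

test_that("with climatological noise the detector still matches the oracle and finds injected days", {
  cfg <- synthClimateConfig(ny = 1, nx = 1, years = 1981:1990,
                            base_mean = 20, seasonal_amplitude = 8,
                            noise_sd = 1.5, seed = 3)
  ref <- generateMeteo(cfg)
  yr <- generateMeteo(synthClimateConfig(ny = 1, nx = 1, years = 1995,
                                         base_mean = 20,
                                         seasonal_amplitude = 8,
                                         noise_sd = 1.5, seed = 4))
  yr <- injectHeatwave(yr, heatwaveSpec("1995-07-05", 5, 15))
  to_series <- function(f) {
    tm <- dailyTmax(f)
    data.frame(region = "A", date = tm$dates, tmax = tm$values[, 1])
  }
  thr <- computeThresholds(to_series(ref))
  sr <- to_series(yr)
  cat <- detectEvents(sr, thr)
  exceed <- sr$tmax > thr$threshold[match(climDoy(sr$date), thr$doy)]
  oracle <- brute_force_events(sr$date, exceed)
  expect_equal(cat$start, oracle$start)
  expect_equal(cat$duration, oracle$duration)
  injected <- as.Date("1995-07-05") + 0:4
  covered <- unlist(lapply(seq_len(nrow(cat)), function(i)
    as.list(cat$start[i] + 0:(cat$duration[i] - 1))))
  expect_true(all(as.numeric(injected) %in% unlist(covered)))
})

test_that("catalogue statistics summarise counts, durations and area affected", {
  thr <- computeThresholds(data.frame(region = rep(c("A", "B"),
                                                   each = 731),
                                      date = rep(year_days(1991, 1992), 2),
                                      tmax = 20))
  dates <- year_days(1995)
  tmA <- rep(15, 365); tmA[c(121:124, 186:193)] <- 25  # May 4d, Jul 8d
  tmB <- rep(15, 365); tmB[186:188] <- 25
  series <- rbind(data.frame(region = "A", date = dates, tmax = tmA),
                  data.frame(region = "B", date = dates, tmax = tmB))
  cat <- detectEvents(series, thr)
  st <- catalogueStats(cat, regions = c("A", "B"))
  expect_equal(st$events_per_year$n, 3L)
  dbs <- st$duration_by_season
  expect_equal(dbs$mean_duration[dbs$season == "summer"], (8 + 3) / 2)
  expect_equal(dbs$mean_duration[dbs$season == "non-summer"], 4)
  aa <- st$area_affected
  expect_equal(max(aa$pct_regions), 100)  # Jul 5-7: both regions active
  expect_equal(aa$pct_regions[aa$date == dates[121]], 50)
  # empty catalogue gives zero counts and an identically zero share
  empty <- detectEvents(data.frame(region = "A", date = dates, tmax = 10),
                        computeThresholds(data.frame(
                          region = "A", date = year_days(1991, 1992),
                          tmax = 20)))
  st0 <- catalogueStats(empty, regions = c("A", "B"), dates = dates)
  expect_equal(nrow(st0$events_per_year), 0L)
  expect_true(all(st0$area_affected$pct_regions == 0))
})

test_that("WBDD accumulates working-hour exceedance over heatwave days only", {
  thr <- computeThresholds(data.frame(region = "A",
                                      date = year_days(1991, 1992),
                                      tmax = 20))
  dates <- year_days(1995)
  tm <- rep(15, 365); tm[150:152] <- 25
  cat <- detectEvents(data.frame(region = "A", date = dates, tmax = tm),
                      thr)
  wb <- expand.grid(date = dates[148:155], hour = 0:23)
  wb$region <- "A"
  wb$wbgt <- 26                       # at threshold: zero exceedance
  res <- computeWBDD(wb, cat)
  expect_equal(res$catalogue$wbdd, 0)
  # one degree above threshold during working hours on one event day
  wb$wbgt[wb$date == dates[150] & wb$hour %in% 9:16] <- 27
  res <- computeWBDD(wb, cat)
  expect_equal(res$catalogue$wbdd, 1)
  # a hot hour outside the catalogued days contributes nothing
  wb$wbgt[wb$date == dates[148]] <- 30
  res2 <- computeWBDD(wb, cat)
  expect_equal(res2$catalogue$wbdd, res$catalogue$wbdd)
  expect_equal(res2$region_year$wbdd, 1)
  # missing working hours raise a coverage error
  expect_error(computeWBDD(wb[wb$hour != 10, ], cat), "coverage")
})

test_that("WBDD is additive over disjoint sub-catalogues", {
  thr <- computeThresholds(data.frame(region = "A",
                                      date = year_days(1991, 1992),
                                      tmax = 20))
  dates <- year_days(1995)
  tm <- rep(15, 365); tm[100:104] <- 25; tm[200:206] <- 25
  cat <- detectEvents(data.frame(region = "A", date = dates, tmax = tm),
                      thr)
  wb <- expand.grid(date = dates[c(100:104, 200:206)], hour = 0:23)
  wb$region <- "A"
  set.seed(7)
  wb$wbgt <- 26 + runif(nrow(wb), 0, 4)
  total <- computeWBDD(wb, cat)$region_year$wbdd
  parts <- vapply(1:2, function(i) {
    sub <- cat[i, , drop = FALSE]
    class(sub) <- class(cat)
    computeWBDD(wb, sub)$region_year$wbdd
  }, numeric(1))
  expect_equal(total, sum(parts))
})
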