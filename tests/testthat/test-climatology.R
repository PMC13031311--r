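test_that("daily mean temperature is the min/max midpoint and rejects inverted records", {
  expect_equal(daily_mean_temperature(0, 10), 5.0)
  expect_equal(daily_mean_temperature(-3, -3), -3.0)
  expect_equal(daily_mean_temperature(-10.4, 2.2), -4.1)
  expect_warning(out <- daily_mean_temperature(5, 2), "tmin > tmax")
  expect_true(is.na(out))
})

test_that("day-of-year index maps leap and non-leap years onto 1..365", {
  expect_equal(day_of_year_index(as.Date("1963-01-01")), 1L)
  expect_equal(day_of_year_index(as.Date("1963-03-01")), 60L)
  expect_equal(day_of_year_index(as.Date("1964-02-28")), 59L)
  expect_equal(day_of_year_index(as.Date("1964-02-29")), 59L)  # shares 59
  expect_equal(day_of_year_index(as.Date("1964-03-01")), 60L)
  expect_equal(day_of_year_index(as.Date("1964-12-31")), 365L)
  expect_equal(day_of_year_index(as.Date("1963-12-31")), 365L)
  # codomain over two full years
  all_days <- seq(as.Date("1964-01-01"), as.Date("1965-12-31"), by = "day")
  idx <- day_of_year_index(all_days)
  expect_true(all(idx >= 1 & idx <= 365))
  expect_equal(sort(unique(idx)), 1:365)
})

test_that("station eligibility counts years with enough valid records", {
  mk <- function(years, days_per_year) {
    data.table::rbindlist(lapply(years, function(y) {
      d <- seq(as.Date(sprintf("%d-01-01", y)), by = "day", length.out = days_per_year)
      data.table::data.table(date = d, tmin = 1, tmax = 5)
    }))
  }
  expect_true(station_is_eligible(mk(1933:1971, 365), c(1933, 1971)))
  expect_false(station_is_eligible(mk(1933:1961, 365), c(1933, 1971)))  # 29 years
  expect_true(station_is_eligible(mk(1933:1962, 180), c(1933, 1971)))   # 30 years at the floor
  expect_false(station_is_eligible(mk(1933:1962, 179), c(1933, 1971)))
})

test_that("constant series fits a flat climatology with zero residual SD", {
  dates <- seq(as.Date("1940-01-01"), as.Date("1949-12-31"), by = "day")
  rec <- data.table::data.table(date = dates, tmin = 8, tmax = 8)
  m <- fit_station_climatology(rec, "const", period = c(1940, 1949))
  expect_equal(m$residual_sd, 0, tolerance = 1e-10)
  expect_equal(unname(expected_temperature(m, as.Date("1945-07-15"))), 8, tolerance = 1e-8)
  expect_equal(unname(expected_at_doy(m, 1:365)), rep(8, 365), tolerance = 1e-8)
})

test_that("degree-4 fit tracks a seasonal harmonic as well as the dense-grid oracle", {
  # independent dense-grid least-squares oracle on the raw day index: for a
  # cosine of amplitude A the best degree-4 L2 fit has max error ~0.104*A
  doy <- 1:365
  for (amp in c(3.5, 7)) {
    truth <- 9 + amp * cos(2 * pi * (doy - 197) / 365)
    oracle <- lm(truth ~ poly(doy, 4))
    oracle_max_err <- max(abs(fitted(oracle) - truth))
    rec <- harmonic_station(amp = amp)
    m <- fit_station_climatology(rec, "H001", period = c(1940, 1949))
    err <- expected_at_doy(m, doy) - truth
    # implementation achieves the oracle's accuracy (up to leap-day weighting)
    expect_lt(max(abs(err)), oracle_max_err + 0.05)
    expect_lt(max(abs(fitted(oracle) - expected_at_doy(m, doy))), 0.05)
    # peak-day expectation close to the true maximum
    expect_lt(abs(expected_at_doy(m, 197) - (9 + amp)), oracle_max_err + 0.05)
  }
  # frozen oracle value: amplitude 3.5 stays within 0.6 degC everywhere
  truth <- 9 + 3.5 * cos(2 * pi * (doy - 197) / 365)
  expect_lt(max(abs(fitted(lm(truth ~ poly(doy, 4))) - truth)), 0.6)
})

test_that("climatology fitting is idempotent on its own predictions", {
  rec <- harmonic_station(amp = 5)
  m <- fit_station_climatology(rec, "H001", period = c(1940, 1949))
  pred <- expected_temperature(m, rec$date)
  rec2 <- data.table::data.table(date = rec$date, tmin = pred - 2, tmax = pred + 2)
  m2 <- fit_station_climatology(rec2, "H001", period = c(1940, 1949))
  expect_equal(expected_at_doy(m2, 1:365), expected_at_doy(m, 1:365), tolerance = 1e-8)
})

test_that("too few distinct days or rank deficiency raises a station-named error", {
  d <- as.Date(c("1940-01-01", "1940-01-02", "1940-01-03", "1940-01-04"))
  rec <- data.table::data.table(date = d, tmin = 1, tmax = 3)
  expect_error(fit_station_climatology(rec, "SHORTY", period = c(1940, 1949)), "SHORTY")
})

test_that("deviations: worked example, zero series, and residual-mean property", {
  # observed -10 vs expected 3 -> deviation -13
  dates <- seq(as.Date("1940-01-01"), as.Date("1949-12-31"), by = "day")
  rec <- data.table::data.table(date = dates, tmin = 3, tmax = 3)
  m <- fit_station_climatology(rec, "const3", period = c(1940, 1949))
  obs <- data.table::data.table(date = as.Date("1949-01-15"), tmin = -10, tmax = -10)
  dev <- compute_deviations(obs, m)
  expect_equal(dev$deviation, -13, tolerance = 1e-8)

  # observed == expectation everywhere -> all-zero deviations
  pred <- expected_temperature(m, dates)
  obs2 <- data.table::data.table(date = dates, tmin = pred, tmax = pred)
  expect_equal(max(abs(compute_deviations(obs2, m)$deviation)), 0, tolerance = 1e-8)

  # over the fit data, deviations average to zero (OLS with intercept)
  rec3 <- harmonic_station(amp = 6)
  m3 <- fit_station_climatology(rec3, "H001", period = c(1940, 1949))
  dev3 <- compute_deviations(rec3, m3)
  expect_lt(abs(mean(dev3$deviation)), 1e-8)
})

test_that("deviations are invariant to adding a constant to every record (refit absorbs it)", {
  rec <- harmonic_station(amp = 4)
  m1 <- fit_station_climatology(rec, "H001", period = c(1940, 1949))
  rec2 <- data.table::copy(rec)
  rec2$tmin <- rec2$tmin + 2.5
  rec2$tmax <- rec2$tmax + 2.5
  m2 <- fit_station_climatology(rec2, "H001", period = c(1940, 1949))
  d1 <- compute_deviations(rec, m1)
  d2 <- compute_deviations(rec2, m2)
  expect_equal(d1$deviation, d2$deviation, tolerance = 1e-8)
})

test_that("climatology prediction is invariant to the internal day-index rescaling", {
  # naive un-rescaled degree-2 fit on a short well-conditioned series
  set.seed(5)
  dates <- seq(as.Date("1940-01-01"), by = "day", length.out = 200)
  doy <- day_of_year_index(dates)
  y <- 4 + 0.03 * doy - 1e-4 * doy^2 + rnorm(200, 0, 0.1)
  rec <- data.table::data.table(date = dates, tmin = y - 1, tmax = y + 1)
  m <- fit_station_climatology(rec, "S", period = c(1940, 1940), degree = 2)
  naive <- lm(y ~ doy + I(doy^2))
  expect_equal(unname(expected_at_doy(m, 1:200)),
               unname(predict(naive, data.frame(doy = 1:200))), tolerance = 1e-6)
})
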