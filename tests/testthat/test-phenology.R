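test_that("gdh_hour matches the cosine response at its landmarks", {
  expect_equal(gdh_hour(4), 0)
  expect_equal(gdh_hour(14.5), 10.5)
  expect_equal(gdh_hour(25), 21)
  expect_equal(gdh_hour(36), 0)
  expect_equal(gdh_hour(40), 0)
  expect_equal(gdh_hour(-10), 0)
})

test_that("gdh_hour is continuous, peaks at TU and vanishes outside (TB, TC)", {
  th <- seq(-5, 45, by = 0.01)
  v <- gdh_hour(th)
  expect_true(all(v >= 0))
  expect_true(all(v <= 21 + 1e-12))
  expect_equal(th[which.max(v)], 25)
  expect_lt(max(abs(diff(v))), 0.05)  # no jump on a 0.01 degree grid
  expect_true(all(v[th <= 4 | th >= 36] == 0))
  ## scaling by the stress factor
  expect_equal(gdh_hour(25, gdh_params(F = 2)), 42)
})

test_that("the literal printed form is preserved behind form = 'as_printed'", {
  p <- gdh_params(form = "as_printed")
  ## branch 1 literal: F*(TB-TU)/2*(1+cos(pi + pi*(TH-TB)/(TU-TB)))
  expect_equal(gdh_hour(14.5, p), 1 * (4 - 25) / 2 * (1 + cos(3 * pi / 2)))
  expect_lt(gdh_hour(20, p), 0)  # negative, the reason it is audit-only
})

test_that("accumulate_gdh sums the half-open window and is additive", {
  ser <- const_series(25, 24)
  expect_equal(accumulate_gdh(ser, ser$timestamp[1], ser$timestamp[11]), 210)
  expect_equal(accumulate_gdh(ser, ser$timestamp[5], ser$timestamp[5]), 0)
  a <- accumulate_gdh(ser, ser$timestamp[1], ser$timestamp[7])
  b <- accumulate_gdh(ser, ser$timestamp[7], ser$timestamp[20])
  expect_equal(a + b,
               accumulate_gdh(ser, ser$timestamp[1], ser$timestamp[20]))
  cold <- const_series(2, 24)
  expect_equal(accumulate_gdh(cold, cold$timestamp[1], cold$timestamp[24]),
               0)
  expect_error(accumulate_gdh(ser, ser$timestamp[1] - 86400,
                              ser$timestamp[5]),
               class = "pedqtl_bad_window")
})

test_that("chill_hours counts hours in (lower, upper], inclusive upper", {
  ser <- const_series(5, 12)
  expect_equal(chill_hours(ser, ser$timestamp[1], ser$timestamp[11]), 10)
  warm <- const_series(20, 12)
  expect_equal(chill_hours(warm, warm$timestamp[1], warm$timestamp[11]), 0)
  edge <- const_series(7.2, 12)
  expect_equal(chill_hours(edge, edge$timestamp[1], edge$timestamp[11]), 10)
  zero <- const_series(0, 12)  # lower bound is exclusive
  expect_equal(chill_hours(zero, zero$timestamp[1], zero$timestamp[11]), 0)
})

test_that("hourly_from_daily preserves daily extremes and the daily mean", {
  flat <- data.frame(site = "S", date = as.Date("2012-03-01") + 0:2,
                     tmin = 10, tmax = 10)
  hf <- hourly_from_daily(flat)
  expect_equal(nrow(hf), 72)
  expect_true(all(hf$temp_C == 10))
  smooth <- data.frame(site = "S", date = as.Date("2012-03-01") + 0:9,
                       tmin = 5 + sin(1:10), tmax = 15 + sin(1:10))
  hs <- hourly_from_daily(smooth)
  daymax <- tapply(hs$temp_C, as.Date(hs$timestamp), max)
  expect_equal(as.numeric(daymax), smooth$tmax)
  daymin <- tapply(hs$temp_C, as.Date(hs$timestamp), min)
  expect_equal(as.numeric(daymin), smooth$tmin)
  expect_lt(abs(mean(hs$temp_C) - mean((smooth$tmin + smooth$tmax) / 2)), 1)
  expect_error(hourly_from_daily(
    data.frame(site = "S", date = as.Date(c("2012-03-01", "2012-03-03")),
               tmin = 1, tmax = 5)),
    class = "pedqtl_missing_day")
})

test_that("predict_stage_dates is sequential and monotone in CR and HR", {
  ser <- season_series(cold_hours = 1000, warm_hours = 2000)
  p <- predict_stage_dates(600, 500, ser)
  ## release exactly when the 600th qualifying cold hour is reached
  expect_equal(p$release, ser$timestamp[600])
  ## heat only accumulates after release (cold block gives no GDH at 5 C < TB+)
  expect_gt(as.numeric(p$flowering - p$release), 0)
  ## tiny heat requirement: flowering collapses onto the release date
  p0 <- predict_stage_dates(600, 1e-9, ser)
  expect_equal(p0$flowering_date, p0$release_date)
  ## doubling HR never advances the date; larger CR never advances release
  p2 <- predict_stage_dates(600, 1000, ser)
  expect_gte(as.numeric(p2$flowering), as.numeric(p$flowering))
  p3 <- predict_stage_dates(900, 500, ser)
  expect_gte(as.numeric(p3$release), as.numeric(p$release))
  expect_error(predict_stage_dates(5000, 500, ser),
               class = "pedqtl_unfulfilled")
  expect_error(predict_stage_dates(600, 1e9, ser),
               class = "pedqtl_unfulfilled")
})

test_that("derive_traits computes BB_CD, BB_GDH and Delta_GDH as defined", {
  ser <- const_series(15, 24 * 120, start = "2012-01-01 00:00:00")
  obs <- data.frame(tree = "t1", genotype = "g1", site = "S", year = 2012,
                    budbreak_date = as.Date("2012-02-01"),
                    flowering_date = as.Date("2012-02-11"))
  ref <- data.frame(site = "S", year = 2012,
                    release_date = as.Date("2012-01-20"))
  tt <- derive_traits(obs, ref, list(S = ser))
  expect_equal(tt$BB_CD, 32L)  # 1 February counted from Jan 1 = 1
  expect_equal(tt$BB_GDH, 12 * 24 * gdh_hour(15))
  expect_equal(tt$Delta_GDH, 10 * 24 * gdh_hour(15))
  ## budbreak on the reference release date gives zero heat
  obs$budbreak_date <- as.Date("2012-01-20")
  expect_equal(derive_traits(obs, ref, list(S = ser))$BB_GDH, 0)
  ## flowering at budbreak gives zero Delta_GDH
  obs$flowering_date <- obs$budbreak_date
  expect_equal(derive_traits(obs, ref, list(S = ser))$Delta_GDH, 0)
  ## budbreak before the reference release is flagged and reported as 0
  obs$budbreak_date <- as.Date("2012-01-10")
  obs$flowering_date <- as.Date("2012-02-11")
  expect_warning(tt2 <- derive_traits(obs, ref, list(S = ser)),
                 "before the reference")
  expect_equal(tt2$BB_GDH, 0)
  expect_true(tt2$bb_before_release)
})
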