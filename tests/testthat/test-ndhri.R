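# Core index: bar areas, circadian segmentation, daily NDHRI, stay summaries.

test_that("window areas follow the 5-min bar rule", {
  expect_equal(compute_window_area(rep(80, 96)), 96 * 5 * 80) # full 8-h night
  expect_equal(compute_window_area(60), 300)
  expect_equal(compute_window_area(numeric(0)), 0)
})

test_that("constant heart rate gives NDHRI exactly 0.5", {
  for (hr in c(55, 70, 121.3)) {
    s <- two_level_series(days = 3, day_hr = hr, night_hr = hr)
    d <- compute_daily_ndhri(s)
    expect_true(all(d$usable))
    expect_equal(d$ndhri, rep(0.5, 3))
  }
})

test_that("two-level days give the closed-form ratio", {
  # night 60 / day 80: (60*480)/(80*960) = 0.375
  d <- compute_daily_ndhri(two_level_series(days = 2, day_hr = 80,
                                            night_hr = 60))
  expect_equal(d$ndhri, rep(28800 / 76800, 2))
  # general dip d: NDHRI = (1 - d)/2, to numerical identity
  for (dip in seq(0.1, 0.9, by = 0.2)) {
    s <- two_level_series(days = 1, day_hr = 100, night_hr = 100 * (1 - dip))
    got <- compute_daily_ndhri(s)$ndhri
    expect_lt(abs(got - (1 - dip) / 2), 1e-12)
  }
})

test_that("NDHRI is invariant to rescaling heart rate", {
  set.seed(5)
  s <- random_gap_series(1L, days = 2, drop = 0.1)
  base <- compute_daily_ndhri(s)
  for (c in c(0.5, 1.3, 7)) {
    sc <- s; sc$heart_rate <- c * sc$heart_rate
    expect_equal(compute_daily_ndhri(sc)$ndhri, base$ndhri)
  }
})

test_that("raising a night slot raises NDHRI; raising a day slot lowers it", {
  set.seed(6)
  s <- two_level_series(days = 1, day_hr = 80, night_hr = 70)
  base <- compute_daily_ndhri(s)$ndhri
  night_idx <- which(((s$t_min - 360) %% 1440) >= 960)
  day_idx <- which(((s$t_min - 360) %% 1440) < 960)
  for (i in sample(night_idx, 3)) {
    up <- s; up$heart_rate[i] <- up$heart_rate[i] + 10
    expect_gt(compute_daily_ndhri(up)$ndhri, base)
  }
  for (i in sample(day_idx, 3)) {
    up <- s; up$heart_rate[i] <- up$heart_rate[i] + 10
    expect_lt(compute_daily_ndhri(up)$ndhri, base)
  }
})

test_that("vectorized daily areas match the per-bar loop oracle", {
  set.seed(7)
  for (r in 1:50) {
    s <- random_gap_series(r, days = sample(2:4, 1), drop = runif(1, 0.1, 0.6))
    got <- compute_daily_ndhri(s)
    want <- brute_daily(s)
    expect_equal(nrow(got), nrow(want))
    expect_lt(max(abs(got$night_area - want$night_area)), 1e-12)
    expect_lt(max(abs(got$day_area - want$day_area)), 1e-12)
    expect_equal(got$night_coverage, want$night_coverage)
    expect_equal(got$day_coverage, want$day_coverage)
  }
})

test_that("area-ratio NDHRI equals the duration-weighted mean identity", {
  # on a fully covered day: ndhri = (mean night HR * 480)/(mean day HR * 960)
  set.seed(8)
  for (r in 1:20) {
    s <- two_level_series(days = 1)
    s$heart_rate <- runif(nrow(s), 50, 150)
    night <- ((s$t_min - 360) %% 1440) >= 960
    want <- (mean(s$heart_rate[night]) * 480) / (mean(s$heart_rate[!night]) * 960)
    expect_lt(abs(compute_daily_ndhri(s)$ndhri - want), 1e-12)
  }
})

test_that("circadian segmentation pairs each daytime with the following night", {
  # full coverage from 06:00 day 1 to 06:00 day 3 -> 2 whole circadian days
  s <- two_level_series(days = 2)
  seg <- segment_circadian_days(s)
  expect_equal(nrow(seg), 4) # 2 days x 2 windows
  expect_true(all(seg$coverage == 1))
  d <- compute_daily_ndhri(s)
  expect_equal(sum(d$usable), 2)

  # admitted 23:00: the first circadian day has an empty daytime window
  start <- t_at(1, 23)
  t <- seq(start, start + 2 * 1440 - 5, by = 5)
  s2 <- data.frame(stay_id = 1L, t_min = t, heart_rate = 80)
  d2 <- compute_daily_ndhri(s2)
  expect_false(d2$usable[1])
  expect_equal(d2$day_coverage[1], 0)

  # empty series -> zero windows, no crash
  empty <- data.frame(stay_id = integer(0), t_min = numeric(0),
                      heart_rate = numeric(0))
  expect_equal(nrow(segment_circadian_days(empty)), 0)
  expect_equal(nrow(compute_daily_ndhri(empty)), 0)
})

test_that("segmentation rejects discharge before admission", {
  s <- two_level_series(days = 1)
  expect_error(segment_circadian_days(s, admit_time = t_at(2, 6),
                                      discharge_time = t_at(1, 6)),
               "discharge before admission")
})

test_that("a day with night data but zero day area is unusable, not an error", {
  start <- t_at(1, 22)
  t <- seq(start, start + 8 * 60 - 5, by = 5) # night window only
  s <- data.frame(stay_id = 1L, t_min = t, heart_rate = 75)
  d <- compute_daily_ndhri(s)
  expect_true(all(!d$usable))
  expect_true(all(is.na(d$ndhri)))
})

test_that("stay summaries average usable days and count range membership", {
  daily <- data.frame(stay_id = 1L, day_index = 1:3, cal_day = 1:3,
                      night_area = 1, day_area = 1,
                      ndhri = c(0.40, 0.44, 0.48),
                      night_coverage = 1, day_coverage = 1, usable = TRUE)
  s <- summarize_stays(daily, 0.40, 0.45)
  expect_equal(s$mean_ndhri, 0.44)
  expect_equal(s$prop_in_range, 2 / 3) # 0.40 counts: closed interval

  one <- daily[2, ]; one$ndhri <- 0.42
  s1 <- summarize_stays(one, 0.40, 0.45)
  expect_equal(s1$mean_ndhri, 0.42)
  expect_equal(s1$prop_in_range, 1)

  none <- daily; none$usable <- FALSE
  s0 <- summarize_stays(none, 0.40, 0.45)
  expect_false(s0$usable)
  expect_equal(s0$n_usable_days, 0L)
  expect_true(is.na(s0$mean_ndhri))
})
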