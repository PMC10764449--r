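test_that("constant and piecewise-constant traces split exactly", {
  cst <- activity_trace(rep(0.3, 2 * 1440))
  d <- split_day_night(cst)
  expect_equal(d$light_mean, c(0.3, 0.3))
  expect_equal(d$dark_mean, c(0.3, 0.3))

  day <- c(rep(0.2, 720), rep(0.8, 720))
  pw <- activity_trace(rep(day, 3))
  d <- split_day_night(pw)
  expect_equal(d$light_mean, rep(0.2, 3))
  expect_equal(d$dark_mean, rep(0.8, 3))
})

test_that("light/dark assignment partitions every sample exactly once", {
  # indicator trace: 1 during light minutes, 0 during dark minutes
  ind <- activity_trace(rep(c(rep(1, 720), rep(0, 720)), 2))
  d <- split_day_night(ind)
  expect_equal(d$light_mean, c(1, 1))
  expect_equal(d$dark_mean, c(0, 0))
  expect_error(activity_trace(rep(0.1, 1000)), "whole number of days")
})

test_that("3-h binning gives 8 bins per day matching brute-force slice means", {
  ramp <- activity_trace((0:1439) / 1440)
  b <- bin_3h(ramp)
  expect_equal(nrow(b), 8)
  expect_equal(b$bin, 0:7)
  brute <- vapply(0:7, function(k) mean(((0:1439) / 1440)[k * 180 + 1:180]),
                  numeric(1))
  expect_equal(b$bin_mean, brute, tolerance = 1e-14)
  # reassembling the bins recovers the 24-h mean
  expect_equal(mean(b$bin_mean), mean(ramp$values), tolerance = 1e-12)
  expect_error(bin_3h(activity_trace(rep(0.5, 2700), period = 32)),
               "does not divide")
})

test_that("period aggregation does calendar arithmetic on post-surgery weeks", {
  p <- activity_preset(c(0.10, 0.07, 0.06, 0.09, 0.52, 0.42, 0.30, 0.20))
  tr <- simulate_activity(p, seed = 2)
  b <- bin_3h(tr)
  agg <- aggregate_bins_by_period(b, study_periods(7))
  expect_setequal(unique(agg$period),
                  c("baseline", "week1", "week2", "week3", "week4"))
  n_days <- tapply(agg$n_days, agg$period, unique)
  expect_equal(n_days[["baseline"]], 7)
  expect_equal(n_days[["week1"]], 7)
  expect_equal(n_days[["week4"]], 6)
  # one-day period equals that day's bins
  one <- aggregate_bins_by_period(b, list(d3 = 3))
  expect_equal(one$mean, b$bin_mean[b$day_index == 3])
  # activity peaks in the 12-15 h bin (bin 4, just after lights-off) everywhere
  peak <- tapply(agg$mean, agg$period, which.max)
  expect_true(all(peak == 5))  # 1-based position of bin 4
  expect_error(aggregate_bins_by_period(b, list(a = 1:3, b = 3:5)), "overlap")
  expect_error(aggregate_bins_by_period(b, list(empty = 999)), "empty")
})

test_that("baseline normalization follows its defining arithmetic", {
  mk <- function(dark) {
    data.frame(day_index = seq_along(dark) - 4L,
               light_mean = 0.1, dark_mean = dark)
  }
  flat <- normalize_to_baseline(mk(rep(0.5, 10)), 3)
  expect_equal(flat$normalized_night, rep(1, 7))
  s <- normalize_to_baseline(mk(c(0.4, 0.5, 0.6, 0.25, rep(0.5, 6))), 3)
  expect_equal(s$normalized_night[1], 0.5)
  expect_error(normalize_to_baseline(mk(c(0, 0, 0, rep(0.5, 7))), 3,
                                     cage_id = "cageX"), "cageX")
  expect_error(normalize_to_baseline(mk(rep(0.5, 3))[-1, ], 3), "fewer than")
})

test_that("baseline normalization is invariant to rescaling the whole trace", {
  p <- activity_preset(c(0.05, 0.04, 0.03, 0.05, 0.26, 0.21, 0.15, 0.10),
                       dip_depth = 0.5, n_days_pre = 3, n_days_post = 5)
  tr <- simulate_activity(p, seed = 9)
  half <- tr
  half$values <- tr$values / 2
  a <- normalize_to_baseline(split_day_night(tr), 3)
  b <- normalize_to_baseline(split_day_night(half), 3)
  expect_equal(a$normalized_night, b$normalized_night, tolerance = 1e-12)
})

test_that("control normalization returns per-animal ratios on the control scale", {
  mk <- function(val) data.frame(day_index = 0:27, normalized_night = val)
  grp <- list(mk(1.2), mk(1.2))
  ctl <- list(mk(1.2), mk(1.2))
  expect_equal(normalize_to_control(grp, ctl), c(1, 1))
  expect_equal(normalize_to_control(list(mk(2.4)), ctl), 2)
  expect_error(normalize_to_control(grp, list(mk(0))), "not positive")
})
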