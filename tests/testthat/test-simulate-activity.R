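template <- c(0.10, 0.07, 0.06, 0.09, 0.52, 0.42, 0.30, 0.20)

test_that("noiseless generator with no injury reproduces the template exactly", {
  p <- activity_preset(template, dip_depth = 0, recovery_gain = 1,
                       noise_sd = 0, n_days_pre = 2, n_days_post = 3)
  tr <- simulate_activity(p, seed = 1)
  b <- bin_3h(tr)
  for (d in unique(b$day_index)) {
    expect_equal(b$bin_mean[b$day_index == d], template, tolerance = 1e-12)
  }
})

test_that("noiseless bin means equal template times the closed-form injury factor", {
  p <- activity_preset(template, dip_depth = 0.6, recovery_tau = 3,
                       recovery_gain = 1.1, noise_sd = 0,
                       n_days_pre = 2, n_days_post = 5)
  tr <- simulate_activity(p, seed = 1)
  b <- bin_3h(tr)
  for (d in unique(b$day_index)) {
    expect_equal(b$bin_mean[b$day_index == d],
                 template * injury_factor(d, p), tolerance = 1e-12)
  }
  # injury factor anchors: 1 pre-surgery, 1 - dip on day 0, gain at infinity
  expect_equal(injury_factor(-1, p), 1)
  expect_equal(injury_factor(0, p), 1 - p$dip_depth)
  expect_equal(injury_factor(1e6, p), p$recovery_gain)
})

test_that("night activity reaches its strict minimum on the surgery day", {
  for (preset in study_activity_presets()) {
    for (seed in c(1, 19, 404)) {
      tr <- simulate_activity(preset, seed = seed)
      d <- split_day_night(tr)
      day0 <- d$dark_mean[d$day_index == 0]
      expect_true(all(day0 < d$dark_mean[d$day_index != 0]))
    }
  }
})

test_that("traces are deterministic in (preset, seed) and bounded in [0, 1]", {
  p <- study_activity_presets()$unilateral_free
  a <- simulate_activity(p, seed = 11)
  b <- simulate_activity(p, seed = 11)
  c <- simulate_activity(p, seed = 12)
  expect_identical(a$values, b$values)
  expect_false(identical(a$values, c$values))
  expect_true(all(a$values >= 0 & a$values <= 1))
  expect_length(a$values, (p$n_days_pre + 1 + p$n_days_post) * 1440)
})

test_that("bilateral-free mice out-recover bilateral-blocked in late normalized nights", {
  presets <- study_activity_presets()
  late_mean <- function(preset, seeds) {
    mean(vapply(seeds, function(s) {
      ns <- normalize_to_baseline(split_day_night(
        simulate_activity(preset, seed = s)), 3)
      mean(ns$normalized_night[ns$day_index >= 20])
    }, numeric(1)))
  }
  free <- late_mean(presets$bilateral_free, 1:40)
  blocked <- late_mean(presets$bilateral_blocked, 101:140)
  expect_gt(free, blocked)
  # closed-form oracle: the generator's expected late injury factors order
  # the same way
  f_free <- mean(injury_factor(20:27, presets$bilateral_free))
  f_blocked <- mean(injury_factor(20:27, presets$bilateral_blocked))
  expect_gt(f_free, f_blocked)
  expect_equal(free / blocked, f_free / f_blocked, tolerance = 0.05)
})

test_that("invalid presets are rejected", {
  expect_error(activity_preset(c(template, 1)), "8 nonnegative")
  expect_error(activity_preset(template, dip_depth = 1.2), "dip_depth")
  expect_error(activity_preset(template, recovery_tau = -1), "recovery_tau")
  expect_error(activity_preset(template, n_days_pre = -2), "nonnegative integers")
  expect_error(activity_preset(c(NA, template[-1])), "finite")
  expect_error(simulate_activity(activity_preset(template)), "seed")
})

test_that("activity traces round-trip through CSV", {
  p <- activity_preset(template, n_days_pre = 1, n_days_post = 1)
  tr <- simulate_activity(p, seed = 4, cage_id = "c1")
  path <- withr::local_tempfile(fileext = ".csv")
  write_activity_csv(tr, path)
  back <- read_activity_csv(path, surgery_day = tr$surgery_day)
  expect_equal(back$values, tr$values, tolerance = 1e-9)
  expect_equal(split_day_night(back), split_day_night(tr), tolerance = 1e-12)
})
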