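test_that("average state curve is the per-epoch mean of awake states", {
  log <- regular_log()
  cv <- average_state_curve(log, c(3, 10))
  expect_equal(cv$rates[cv$times < 7], rep(0, 48))
  expect_equal(cv$rates[cv$times >= 7], rep(1, 36))

  log2 <- regular_log(wake_times = rep(c(6, 8), 8)[1:15])
  cv2 <- average_state_curve(log2, c(3, 10))
  mid <- cv2$times >= 6 & cv2$times < 8
  expect_true(all(abs(cv2$rates[mid] - 0.5) <= 0.5 / 14 + 1e-9))
  expect_equal(unique(cv2$rates[cv2$times < 6]), 0)
  expect_equal(unique(cv2$rates[cv2$times >= 8]), 1)
})

test_that("average state curve errors when no day covers the window", {
  fl <- flags_df()[0, ]
  iv <- schedule_intervals()[0, ]
  log <- build_sleep_log(as_sleep_intervals(iv), fl, "c1", 30, START_DATE)
  expect_error(average_state_curve(log, c(3, 10)), "no non-missing day")
})

test_that("sigmoid fit recovers exact logistic parameters without jitter", {
  cv <- logistic_curve(0, 1, 6.84, 0.26)
  for (seed in c(1, 99)) {
    f <- fit_sigmoid(cv, "rising", n_repeats = 3, jitter_eps = 0, seed = seed)
    expect_lt(abs(f$a - 0), 1e-3)
    expect_lt(abs(f$b - 1), 1e-3)
    expect_lt(abs(f$c - 6.84), 1e-3)
    expect_lt(abs(f$d - 0.26), 1e-3)
  }
})

test_that("a constant wake time yields a step curve with c at the step and d near 0", {
  cv <- mk_curve(as.numeric(seq(3, 10 - 1 / 12, by = 1 / 12) >= 7))
  f <- fit_sigmoid(cv, "rising", n_repeats = 100, jitter_eps = 0.01, seed = 1)
  expect_lt(abs(f$c - 7.0), 1 / 12 + 1e-9)
  expect_lte(f$d, 0.02)
  expect_gte(f$converged_fraction, 0.5)
})

test_that("falling fits return c at the bed step with negative d", {
  x <- seq(18, 26 - 1 / 12, by = 1 / 12)
  f <- fit_sigmoid(mk_curve(as.numeric(x < 21), c(18, 26)), "falling",
                   n_repeats = 100, jitter_eps = 0.01, seed = 1)
  expect_lt(abs(f$c - 21.0), 1 / 12 + 1e-9)
  expect_lt(f$d, 0)
  expect_gte(f$d, -0.02)
})

test_that("alternating bed times average to the midpoint transition", {
  x <- seq(18, 26 - 1 / 12, by = 1 / 12)
  y <- 1 - (0.5 * (x >= 20.5) + 0.5 * (x >= 22.5))
  f <- fit_sigmoid(mk_curve(y, c(18, 26)), "falling", n_repeats = 50,
                   jitter_eps = 0.01, seed = 3)
  expect_lt(abs(f$c - 21.5), 0.25)
})

test_that("constant rate curves are fit failures", {
  expect_error(fit_sigmoid(mk_curve(rep(1, 84)), "rising", seed = 1),
               "constant")
})

test_that("a fitted d tracks the day-to-day spread as sigma * sqrt(3) / pi", {
  set.seed(11)
  cv <- normal_wake_curve(6.84, 0.4, 500)
  f <- fit_sigmoid(cv, "rising", n_repeats = 30, jitter_eps = 0.01, seed = 2)
  target <- 0.4 * sqrt(3) / pi
  expect_lt(abs(f$d - target) / target, 0.15)
})

test_that("fitted |d| increases strictly with the day-to-day spread", {
  set.seed(12)
  ds <- vapply(c(0.1, 0.3, 0.6), function(sg) {
    cv <- normal_wake_curve(6.84, sg, 500)
    fit_sigmoid(cv, "rising", n_repeats = 20, jitter_eps = 0.01, seed = 5)$d
  }, numeric(1))
  expect_true(all(diff(ds) > 0))
})

test_that("jitter-averaged c is stable across seeds", {
  set.seed(13)
  cv <- normal_wake_curve(6.84, 0.3, 14)
  cs <- vapply(1:20, function(s)
    fit_sigmoid(cv, "rising", n_repeats = 100, jitter_eps = 0.01, seed = s)$c,
    numeric(1))
  expect_lt(sd(cs), 0.01)
})

test_that("wake and bed features return the fit's (c, d) on the right scales", {
  log <- regular_log()
  wf <- wake_time_features(log, n_repeats = 30, seed = 1)
  expect_lt(abs(wf[["wake_up_time"]] - 7.0), 1 / 12)
  expect_lte(wf[["wake_up_time_variation"]], 0.02)
  bf <- bed_time_features(log, n_repeats = 30, seed = 1)
  expect_lt(abs(bf[["bed_time"]] - 21.0), 1 / 12)
  expect_lt(bf[["bed_time_variation"]], 0)
  expect_gte(bf[["bed_time_variation"]], -0.02)
})

test_that("late bed times are reported on the extended 24-hour scale", {
  log <- regular_log(bed_times = 25.45, wake_times = 8)  # 01:27
  bf <- bed_time_features(log, n_repeats = 30, seed = 1)
  expect_lt(abs(bf[["bed_time"]] - 25.45), 1 / 12)
})

test_that("a curve with no transition in the window is a fit failure", {
  # afternoon-only sleeper: 13:00-18:00, never asleep in the wake window
  iv <- as_sleep_intervals(daily_extra(start = 13, end = 18))
  log <- build_sleep_log(iv, flags_df(), "c1", 30, START_DATE)
  expect_error(wake_time_features(log, n_repeats = 10, seed = 1), "constant")
  expect_equal(nocturnal_sleep_duration(log), 0)
})

test_that("sleep durations match hand-computed values", {
  log <- regular_log()
  expect_equal(total_sleep_duration(log), 10.0)
  expect_equal(nocturnal_sleep_duration(log), 10.0)
  log_nap <- regular_log(extra = daily_extra(start = 13, end = 13.5))
  expect_equal(total_sleep_duration(log_nap), 10.5)
  expect_equal(nocturnal_sleep_duration(log_nap), 10.0)
  # all awake: flags recorded but no sleep at all
  log_awake <- build_sleep_log(as_sleep_intervals(schedule_intervals()[0, ]),
                               flags_df(), "c1", 30, START_DATE)
  expect_equal(total_sleep_duration(log_awake), 0.0)
})

test_that("a nightly 02:00-02:10 waking reduces nocturnal sleep by 10 minutes", {
  nights <- (-1):13
  iv <- do.call(rbind, lapply(seq_along(nights), function(k) {
    data.frame(child_id = "c1",
               date = START_DATE + nights[k] + c(0, 1),
               start = c(21, 2 + 1 / 6), end = c(26, 7))
  }))
  # drop the lead-in segment that ends before the span starts at 03:00
  iv <- iv[24 * as.numeric(iv$date - START_DATE) + iv$end > 3, ]
  log <- build_sleep_log(as_sleep_intervals(iv), flags_df(), "c1", 30,
                         START_DATE)
  expect_equal(nocturnal_sleep_duration(log), 10 - 1 / 6)
  expect_equal(night_wakings(log), 1.0)
})

test_that("night wakings: zero for uninterrupted nights, reported counts preferred", {
  expect_equal(night_wakings(regular_log()), 0.0)
  log <- regular_log(flags = flags_df(night_wakings = c(rep(0L, 12), 2L, 3L)))
  expect_equal(night_wakings(log), 5 / 14)
})

test_that("evening nap counts maximal sleep episodes touching 15:00-19:00", {
  expect_equal(evening_nap(regular_log()), 0.0)
  log <- regular_log(extra = daily_extra(start = 16, end = 16.5))
  expect_equal(evening_nap(log), 1.0)
  # two episodes on 7 of 14 days: (7 * 2 + 7 * 0) / 14 = 1
  extra <- rbind(daily_extra(start = 15 + 1 / 6, end = 15.5, days = 0:6),
                 daily_extra(start = 18, end = 18 + 1 / 3, days = 0:6))
  expect_equal(evening_nap(regular_log(extra = extra)), 1.0)
})

test_that("flag rates are means over non-missing days", {
  expect_equal(breakfast_rate(regular_log()), 1.0)
  log <- regular_log(flags = flags_df(self_awake = rep(c(1, 0), 7)))
  expect_equal(self_awake_rate(log), 0.5)
})

test_that("extract_features composes the ten variables and is seed-deterministic", {
  log <- regular_log(flags = flags_df(self_awake = rep(c(1, 0), 7)))
  f1 <- extract_features(log, n_repeats = 30, seed = 42)
  f2 <- extract_features(log, n_repeats = 30, seed = 42)
  expect_identical(f1, f2)
  expect_lt(abs(f1$wake_up_time - 7), 1 / 12)
  expect_lte(f1$wake_up_time_variation, 0.02)
  expect_lt(abs(f1$bed_time - 21), 1 / 12)
  expect_gte(f1$bed_time_variation, -0.02)
  expect_equal(f1$total_sleep_duration, 10)
  expect_equal(f1$nocturnal_sleep_duration, 10)
  expect_equal(f1$night_wakings, 0)
  expect_equal(f1$evening_nap, 0)
  expect_equal(f1$breakfast, 1)
  expect_equal(f1$self_awake, 0.5)
})

test_that("feature errors name the failing variable", {
  iv <- as_sleep_intervals(daily_extra(start = 13, end = 18))
  log <- build_sleep_log(iv, flags_df(), "c1", 30, START_DATE)
  expect_error(extract_features(log, n_repeats = 10, seed = 1),
               "feature 'wake_up_time'")
})

test_that("extracted features respect their window and range invariants", {
  sim <- simulate_cohort(simulation_config(list("3" = c(2, 2), "6" = c(2, 2)),
                                           seed = 17))
  coh <- build_cohort(sim$intervals, sim$daily, sim$children, sim$labels)
  res <- extract_cohort_features(coh, n_repeats = 20, seed = 1)
  f <- res$features
  expect_equal(nrow(f), 8)
  expect_true(all(f$wake_up_time > 3 & f$wake_up_time < 10))
  expect_true(all(f$bed_time > 18 & f$bed_time < 26))
  expect_true(all(f$wake_up_time_variation > 0))
  expect_true(all(f$bed_time_variation < 0))
  expect_true(all(f$total_sleep_duration >= 0 & f$total_sleep_duration <= 24))
  expect_true(all(f$nocturnal_sleep_duration >= 0 &
                    f$nocturnal_sleep_duration <= 14))
  expect_true(all(f$breakfast >= 0 & f$breakfast <= 1))
  expect_true(all(f$self_awake >= 0 & f$self_awake <= 1))
  expect_true(all(f$night_wakings >= 0))
})
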