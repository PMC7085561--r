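test_that("default configurations carry the per-item thresholds and limits", {
  cs <- default_detector_config("chair_stand")
  expect_equal(cs$active_enter, -8.0)
  expect_equal(cs$max_duration_s, 30)
  ac <- default_detector_config("arm_curl")
  expect_equal(ac$active_enter, 7.5)
  st <- default_detector_config("two_min_step")
  expect_equal(st$max_duration_s, 120)
  expect_error(default_detector_config("up_and_go"), "arg")
})

test_that("overlapping hysteresis bands are rejected at construction", {
  expect_error(detector_config(active_enter = -1, active_op = "lt",
                               baseline_enter = 2, baseline_op = "abs_lt",
                               max_duration_s = 30),
               "overlap")
})

test_that("detector recovers simulator ground truth across items and noise", {
  for (kind in c("chair_stand", "arm_curl", "two_min_step")) {
    cfg <- default_detector_config(kind)
    for (ns in c(0, 0.2, 0.5)) {
      sim <- simulate_trace(sim_spec(kind, n_reps = 9, noise_sd = ns,
                                     seed = 100 + ns * 10))
      det <- count_repetitions(sim$trace, cfg)
      expect_identical(det$reps, 9L, label = sprintf("%s sd=%g", kind, ns))
      expect_length(det$rep_times, 9)
      expect_true(all(diff(det$rep_times) > 0))
      expect_false(det$incomplete_final_phase)
    }
  }
})

test_that("degenerate and sub-threshold traces count zero repetitions", {
  flat <- gravity_trace(seq(0, 30, by = 0.02), 0, 0, 9.81)
  det <- count_repetitions(flat, default_detector_config("chair_stand"))
  expect_identical(det$reps, 0L)
  expect_false(det$incomplete_final_phase)
  # arm curl excursion peaking below the +7.5 threshold
  tt <- seq(0, 10, by = 0.02)
  y <- -9.8 + 16.8 * exp(-((tt - 5) / 1.2)^2)  # peak +7.0
  tr <- gravity_trace(tt, 0, y, sqrt(pmax(0, 9.81^2 - y^2)))
  expect_identical(count_repetitions(tr, default_detector_config("arm_curl"))$reps, 0L)
})

test_that("a trace ending mid-active-phase leaves the final rep uncounted", {
  sim <- simulate_trace(sim_spec("chair_stand", n_reps = 4, noise_sd = 0))
  s <- sim$trace$samples
  cut <- s[s$t <= sim$rep_boundaries$mid_s[4], ]
  tr <- gravity_trace(cut$t, cut$x, cut$y, cut$z)
  det <- count_repetitions(tr, default_detector_config("chair_stand"))
  expect_identical(det$reps, 3L)
  expect_true(det$incomplete_final_phase)
})

test_that("oscillation inside the hysteresis gap never counts", {
  tt <- seq(0, 20, by = 0.02)
  y <- -5 + 2.5 * sin(2 * pi * tt)  # swings -7.5..-2.5, inside gap [-8, -2]
  tr <- gravity_trace(tt, 0, y, sqrt(pmax(0, 9.81^2 - y^2)))
  det <- count_repetitions(tr, default_detector_config("two_min_step"))
  expect_identical(det$reps, 0L)
})

test_that("appending samples never decreases the count", {
  sim <- simulate_trace(sim_spec("arm_curl", n_reps = 6, noise_sd = 0.4,
                                 seed = 5))
  s <- sim$trace$samples
  cfg <- default_detector_config("arm_curl")
  prev <- 0L
  for (frac in seq(0.2, 1, by = 0.1)) {
    cut <- s[seq_len(ceiling(frac * nrow(s))), ]
    det <- count_repetitions(gravity_trace(cut$t, cut$x, cut$y, cut$z), cfg)
    expect_gte(det$reps, prev)
    prev <- det$reps
  }
})

test_that("samples beyond the time limit never affect the count", {
  sim <- simulate_trace(sim_spec("chair_stand", n_reps = 12, rep_period_s = 3,
                                 noise_sd = 0))
  det <- count_repetitions(sim$trace, default_detector_config("chair_stand"))
  # 1.5 s lead-in + 12 x 3 s exceeds 30 s: only reps completing by 30 s count
  done_by_limit <- sum(sim$rep_boundaries$end_s <= 30)
  expect_identical(det$reps, as.integer(done_by_limit))
  expect_equal(det$truncated_at_s, 30)
  expect_true(all(det$rep_times <= 30))
})

test_that("a trace starting mid-active begins in the ACTIVE state", {
  sim <- simulate_trace(sim_spec("chair_stand", n_reps = 3, noise_sd = 0))
  s <- sim$trace$samples
  tail_ <- s[s$t >= sim$rep_boundaries$mid_s[1], ]
  tr <- gravity_trace(tail_$t - tail_$t[1], tail_$x, tail_$y, tail_$z)
  det <- count_repetitions(tr, default_detector_config("chair_stand"))
  # the interrupted first rep still completes on its return to baseline
  expect_identical(det$reps, 3L)
})

test_that("stopwatch timing rounds half-up to 0.1 s and keeps the fastest trial", {
  expect_equal(stopwatch_time(list(c(0, 5.27), c(0, 5.61))), 5.3)
  expect_equal(stopwatch_time(list(c(0, 6.04))), 6.0)
  expect_equal(stopwatch_time(list(c(0, 5.25), c(0, 5.25))), 5.3)
  expect_equal(stopwatch_time(list(c(2, 8.38), c(1, 6.9))), 5.9)
  expect_error(stopwatch_time(list(c(5, 5))), "exceed")
  expect_error(stopwatch_time(list()), "trial")
})
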