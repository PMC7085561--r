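test_that("trace construction enforces timestamp invariants", {
  expect_error(gravity_trace(numeric(0), 0, 0, 0), "no samples")
  expect_error(gravity_trace(c(0, 0.02, 0.02), 0, 0, 9.81), "increasing")
  expect_error(gravity_trace(c(-1, 0), 0, 0, 9.81), "non-negative")
  tr <- gravity_trace(c(0, 0.02, 0.04), 0, c(0, -4.9, -9.8),
                      c(9.81, sqrt(9.81^2 - 4.9^2), sqrt(9.81^2 - 9.8^2)))
  expect_equal(nrow(tr$samples), 3)
  expect_equal(trace_duration(tr), 0.04)
  expect_null(tr$meta$norm_warnings)
})

test_that("out-of-band vector norms are flagged in meta, not fatal", {
  tr <- gravity_trace(c(0, 0.02), 0, c(0, 0), c(9.81, 20))
  expect_equal(tr$meta$norm_warnings, 2L)
  expect_equal(nrow(tr$samples), 2)
})

test_that("CSV round trip is lossless to 1e-6 and recovers metadata", {
  sim <- simulate_trace(sim_spec("chair_stand", n_reps = 3, noise_sd = 0.3,
                                 seed = 11))
  tr <- sim$trace
  tr$meta$device <- "test-phone"
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace(tr, path)
  back <- read_trace(path)
  expect_equal(back$samples$t, tr$samples$t, tolerance = 1e-6)
  for (ax in c("x", "y", "z"))
    expect_true(max(abs(back$samples[[ax]] - tr$samples[[ax]])) <= 1e-6 + 1e-12)
  expect_equal(back$meta$device, "test-phone")
  expect_equal(back$meta$test_item, "chair_stand")
})

test_that("read_trace reports malformed input precisely", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("t,x,y,z", "0,0,0,9.81", "0.02,0,oops,9.81"), p)
  expect_error(read_trace(p), "line 3")
  writeLines(c("t,x,y,z", "0,0,9.81"), p)
  expect_error(read_trace(p), "line 2")
  writeLines("t,x,y,z", p)
  expect_error(read_trace(p), "no samples")
  writeLines(c("t,x,y,z", "0.02,0,0,9.81", "0,0,0,9.81"), p)
  expect_error(read_trace(p), "increasing")
  expect_error(read_trace(file.path(tempdir(), "absent.csv")), "not found")
})

test_that("read_trace supports remapped column names", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,ax,ay,az", "0,0,0,9.81", "0.02,0,-4.9,8.5"), p)
  tr <- read_trace(p, columns = c(t = "time", x = "ax", y = "ay", z = "az"))
  expect_equal(tr$samples$y, c(0, -4.9))
})

test_that("write_trace refuses unwritable paths", {
  sim <- simulate_trace(sim_spec("arm_curl", n_reps = 2, noise_sd = 0))
  expect_error(write_trace(sim$trace, file.path(tempdir(), "no", "such", "dir", "x.csv")),
               "cannot write")
})

test_that("smoothing is a length-preserving centred moving average", {
  tr <- gravity_trace(seq(0, 0.04, by = 0.02), 0, c(0, 9, 0), 9.81)
  sm <- smooth_trace(tr, 3)
  expect_equal(sm$samples$y[2], 3.0)          # (0 + 9 + 0) / 3
  expect_equal(nrow(sm$samples), 3)
  expect_identical(smooth_trace(tr, 1), tr)   # window 1 is the identity
  const <- gravity_trace(seq(0, 1, by = 0.1), 1, 2, 9.6)
  expect_equal(smooth_trace(const, 5)$samples$y, const$samples$y)
  expect_error(smooth_trace(tr, 4), "odd")
  expect_error(smooth_trace(tr, 0), "odd|positive")
})

test_that("smoothing is linear and preserves the mean of constant-extended signals", {
  set.seed(3)
  y <- c(rep(0.5, 5), rnorm(40), rep(0.5, 5))
  z <- c(rep(9.6, 5), 9.6 + rnorm(40, sd = 0.1), rep(9.6, 5))
  tr <- gravity_trace(seq_along(y) / 50, 0.1, y, z)
  sm <- smooth_trace(tr, 5)
  expect_equal(mean(sm$samples$y), mean(tr$samples$y), tolerance = 1e-9)
  expect_equal(mean(sm$samples$z), mean(tr$samples$z), tolerance = 1e-9)
  # linearity: smoothing y + 2z equals smoothed y + 2 * smoothed z
  tr2 <- gravity_trace(tr$samples$t, 0.1, y + 2 * z, z)
  sm2 <- smooth_trace(tr2, 5)
  expect_equal(sm2$samples$y, sm$samples$y + 2 * sm$samples$z,
               tolerance = 1e-12)
})
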