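test_that("Cronbach's alpha matches the published two-method values", {
  m <- fixture_matrices()
  expect_equal(round(cronbach_alpha(m$chair_stand), 2), 0.93)
  expect_equal(round(cronbach_alpha(m$arm_curl), 2), 0.99)
  expect_equal(round(cronbach_alpha(m$two_min_step), 2), 0.98)
  expect_equal(round(cronbach_alpha(m$up_and_go), 2), 0.97)
  # against the independent elementwise oracle
  for (code in names(m))
    expect_equal(cronbach_alpha(m[[code]]), oracle_alpha(m[[code]]),
                 tolerance = 1e-12)
})

test_that("alpha degenerate cases behave as defined", {
  ident <- cbind(c(1, 4, 2, 5), c(1, 4, 2, 5))
  expect_equal(cronbach_alpha(ident), 1.0)
  expect_error(cronbach_alpha(cbind(c(1, 1, 1), c(2, 2, 2))),
               "zero variance")
  expect_error(cronbach_alpha(cbind(1:2, 2:3)), "3 subjects")
  expect_error(cronbach_alpha(matrix(1:6, ncol = 1)), "2 raters")
  expect_error(cronbach_alpha(cbind(c(1, NA, 3), 1:3)), "missing")
})

test_that("ICC point estimates agree with the brute-force ANOVA oracle", {
  set.seed(42)
  for (rep_i in 1:100) {
    X <- random_rating_matrix()
    for (model in c("oneway_random", "twoway_consistency"))
      for (unit in c("single", "average"))
        expect_equal(icc(X, model, unit)$icc, oracle_icc(X, model, unit),
                     tolerance = 1e-9)
  }
})

test_that("for two raters the consistency/average ICC is Cronbach's alpha", {
  set.seed(7)
  for (rep_i in 1:100) {
    X <- random_rating_matrix(k = 2)
    expect_equal(icc(X, "twoway_consistency", "average")$icc,
                 cronbach_alpha(X), tolerance = 1e-12)
  }
})

test_that("the two ICC families differ as documented on the case study", {
  m <- fixture_matrices()
  expect_equal(icc(m$chair_stand)$icc, cronbach_alpha(m$chair_stand),
               tolerance = 1e-12)
  ow <- icc(m$chair_stand, model = "oneway_random", unit = "single")
  expect_equal(ow$icc, 0.5644, tolerance = 1e-4)
  expect_identical(icc(cbind(c(1, 3, 2, 5), c(1, 3, 2, 5)))$icc, 1)
  expect_error(icc(cbind(c(2, 2, 2), c(2, 2, 2))), "no between-subject")
})

test_that("ICC confidence bounds bracket the estimate and narrow with n", {
  m <- fixture_matrices()
  for (code in names(m))
    for (model in c("oneway_random", "twoway_consistency"))
      for (unit in c("single", "average")) {
        r <- icc(m[[code]], model, unit)
        expect_lte(r$ci_low, r$icc + 1e-12)
        expect_gte(r$ci_high, r$icc - 1e-12)
      }
  set.seed(11)
  width_at_n <- function(n) {
    w <- replicate(30, {
      subj <- rnorm(n, sd = 2)
      X <- cbind(subj + rnorm(n), subj + rnorm(n))
      r <- icc(X)
      r$ci_high - r$ci_low
    })
    median(w)
  }
  widths <- vapply(c(5, 10, 50), width_at_n, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("Bland-Altman summarises paired differences with 1.96 SD limits", {
  m <- fixture_matrices()
  ba <- bland_altman(m$chair_stand[, "manual"], m$chair_stand[, "sensor"])
  expect_equal(ba$mean_diff, 13 / 7)
  expect_equal(ba$loa_high - ba$mean_diff, 1.96 * ba$sd_diff)
  same <- bland_altman(c(3, 5, 8), c(3, 5, 8))
  expect_equal(same$mean_diff, 0)
  expect_equal(same$sd_diff, 0)
  ba2 <- bland_altman(c(10, 12), c(8, 12))
  expect_equal(ba2$mean_diff, 1)
  expect_equal(ba2$points$mean, c(9, 12))
  expect_equal(ba2$points$diff, c(2, 0))
})

test_that("interpretation bands follow the published cut-offs, boundaries down", {
  expect_identical(unname(interpret_reliability(0.93, 0.93)),
                   c("excellent", "excellent"))
  expect_identical(unname(interpret_reliability(0.3, 0.4)),
                   c("poor", "unacceptable"))
  expect_identical(unname(interpret_reliability(0.75, 0.9)),
                   c("fair-to-good", "poor-to-good"))
  expect_identical(unname(interpret_reliability(0.4, 0.5)),
                   c("poor", "unacceptable"))
})

test_that("the agreement report reproduces the case-study table shape", {
  rep <- agreement_report()
  expect_identical(rep$test_code, sft_items()$code)
  expect_identical(rep$n, rep(7L, 6))
  expect_equal(round(rep$icc, 2), round(rep$cronbach_alpha, 2))
  expect_true(all(rep$alpha_label == "excellent"))
  expect_true(all(rep$ci_low <= rep$icc & rep$icc <= rep$ci_high))
})

test_that("incomplete paired fixtures fail loudly, naming the hole", {
  pairs <- case_study_results()
  broken <- pairs[!(pairs$subject_id == 3 & pairs$test_code == "arm_curl" &
                      pairs$method == "sensor"), ]
  expect_error(agreement_report(broken), "arm_curl.*3|3.*arm_curl")
  expect_error(agreement_report(pairs[, c("subject_id", "value")]),
               "columns")
})
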