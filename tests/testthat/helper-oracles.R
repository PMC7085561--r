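# Independent brute-force oracles used to cross-check the reliability
# statistics: explicit elementwise sums of squares, no shared code with
# the package implementation.

oracle_anova <- function(X) {
  n <- nrow(X); k <- ncol(X)
  gm <- sum(X) / (n * k)
  ssb <- 0
  for (i in seq_len(n)) ssb <- ssb + k * (sum(X[i, ]) / k - gm)^2
  ssw <- 0
  for (i in seq_len(n)) {
    mi <- sum(X[i, ]) / k
    for (j in seq_len(k)) ssw <- ssw + (X[i, j] - mi)^2
  }
  ssc <- 0
  for (j in seq_len(k)) ssc <- ssc + n * (sum(X[, j]) / n - gm)^2
  sse <- 0
  for (i in seq_len(n)) for (j in seq_len(k)) {
    mi <- sum(X[i, ]) / k
    mj <- sum(X[, j]) / n
    sse <- sse + (X[i, j] - mi - mj + gm)^2
  }
  list(MSB = ssb / (n - 1), MSW = ssw / (n * (k - 1)),
       MSE = sse / ((n - 1) * (k - 1)), n = n, k = k)
}

oracle_icc <- function(X, model, unit) {
  a <- oracle_anova(X)
  denom <- if (model == "oneway_random") a$MSW else a$MSE
  if (unit == "single") (a$MSB - denom) / (a$MSB + (a$k - 1) * denom)
  else (a$MSB - denom) / a$MSB
}

oracle_alpha <- function(X) {
  k <- ncol(X)
  item_var <- numeric(k)
  for (j in seq_len(k)) item_var[j] <- var(X[, j])
  k / (k - 1) * (1 - sum(item_var) / var(rowSums(X)))
}

random_rating_matrix <- function(n = NULL, k = NULL) {
  if (is.null(n)) n <- sample(5:8, 1)
  if (is.null(k)) k <- sample(2:3, 1)
  subj <- rnorm(n, sd = 2)
  matrix(rep(subj, k) + rnorm(n * k), nrow = n, ncol = k)
}

# the case-study fixture as per-item n x 2 matrices
fixture_matrices <- function() {
  pairs <- case_study_results()
  out <- list()
  for (code in unique(pairs$test_code)) {
    sub <- pairs[pairs$test_code == code, ]
    man <- sub$value[sub$method == "manual"][order(sub$subject_id[sub$method == "manual"])]
    sen <- sub$value[sub$method == "sensor"][order(sub$subject_id[sub$method == "sensor"])]
    out[[code]] <- cbind(manual = man, sensor = sen)
  }
  out
}

# published agreement-table values (2 dp) per item, battery order
printed_alpha <- c(chair_stand = 0.93, arm_curl = 0.99, two_min_step = 0.98,
                   sit_reach = 0.99, back_scratch = 0.99, up_and_go = 0.97)
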