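#' Cronbach's alpha
#'
#' Internal-consistency coefficient over an n-subjects-by-k-raters matrix,
#' `alpha = k/(k-1) * (1 - sum(var_i) / var(row totals))`, with sample
#' (n-1) variance denominators. For k = 2 raters this equals the two-way
#' consistency, average-measures intraclass correlation.
#'
#' @param data Numeric matrix or data frame, subjects in rows (n >= 3),
#'   raters/methods in columns (k >= 2), no missing values.
#' @return Alpha (a real number <= 1; negative values are possible for
#'   pathological data).
#' @examples
#' manual <- c(14, 15, 12, 14, 10, 16, 12)
#' sensor <- c(12, 13, 12, 13, 8, 13, 9)
#' round(cronbach_alpha(cbind(manual, sensor)), 2)  # 0.93
#' @export
cronbach_alpha <- function(data) {
  X <- as_rating_matrix(data)
  k <- ncol(X)
  vt <- stats::var(rowSums(X))
  if (vt == 0)
    stop("undefined statistic: zero variance of row totals", call. = FALSE)
  k / (k - 1) * (1 - sum(apply(X, 2, stats::var)) / vt)
}

as_rating_matrix <- function(data) {
  X <- as.matrix(data)
  storage.mode(X) <- "double"
  if (anyNA(X)) stop("missing values not allowed (listwise completeness required)",
                     call. = FALSE)
  if (nrow(X) < 3L) stop("need at least 3 subjects", call. = FALSE)
  if (ncol(X) < 2L) stop("need at least 2 raters/methods", call. = FALSE)
  X
}

#' Intraclass correlation coefficient with F-based confidence interval
#'
#' Two ICC families are implemented, both from the standard ANOVA mean
#' squares:
#' \describe{
#'   \item{`oneway_random`}{subjects are the only factor; with `MSB`
#'     between-subject and `MSW` within-subject mean squares,
#'     single = (MSB - MSW) / (MSB + (k-1) MSW), average = (MSB - MSW)/MSB.}
#'   \item{`twoway_consistency`}{subjects and raters are crossed; with
#'     `MSE` the two-way residual mean square,
#'     single = (MSB - MSE) / (MSB + (k-1) MSE), average = (MSB - MSE)/MSB.
#'     The average-measures form equals Cronbach's alpha.}
#' }
#' Confidence bounds use the exact F pivots for the chosen form
#' (`F = MSB/MSW` on (n-1, n(k-1)) df, or `F = MSB/MSE` on
#' (n-1, (n-1)(k-1)) df).
#'
#' @param data n x k matrix as in [cronbach_alpha()].
#' @param model `"twoway_consistency"` (default) or `"oneway_random"`.
#' @param unit `"average"` (default) or `"single"` measures.
#' @param conf Confidence level (default 0.95).
#' @return List of class `icc_result`: `icc`, `icc_model`, `icc_unit`,
#'   `ci_low`, `ci_high`, `conf`, `n`, `k`, `fvalue`.
#' @examples
#' m <- cbind(a = c(14, 15, 12, 14, 10, 16, 12),
#'            b = c(12, 13, 12, 13, 8, 13, 9))
#' icc(m)$icc                              # 0.928 (equals alpha)
#' icc(m, model = "oneway_random", unit = "single")$icc  # 0.564
#' @export
icc <- function(data, model = c("twoway_consistency", "oneway_random"),
                unit = c("average", "single"), conf = 0.95) {
  model <- match.arg(model)
  unit <- match.arg(unit)
  stopifnot(conf > 0, conf < 1)
  X <- as_rating_matrix(data)
  n <- nrow(X)
  k <- ncol(X)
  gm <- mean(X)
  rm_ <- rowMeans(X)
  MSB <- k * sum((rm_ - gm)^2) / (n - 1)
  if (MSB == 0)
    stop("undefined statistic: no between-subject variance", call. = FALSE)
  if (model == "oneway_random") {
    MSW <- sum((X - rm_)^2) / (n * (k - 1))
    Fv <- MSB / MSW
    df2 <- n * (k - 1)
    denom <- MSW
  } else {
    cm <- colMeans(X)
    resid <- sweep(sweep(X, 1, rm_), 2, cm) + gm
    MSE <- sum(resid^2) / ((n - 1) * (k - 1))
    Fv <- MSB / MSE
    df2 <- (n - 1) * (k - 1)
    denom <- MSE
  }
  est <- if (unit == "single") (MSB - denom) / (MSB + (k - 1) * denom)
         else (MSB - denom) / MSB
  alpha2 <- (1 - conf) / 2
  # degenerate residual (perfect agreement): F is infinite, CI collapses at 1
  if (denom == 0) {
    fl <- fu <- Inf
  } else {
    fl <- Fv / stats::qf(1 - alpha2, n - 1, df2)
    fu <- Fv * stats::qf(1 - alpha2, df2, n - 1)
  }
  ci <- if (unit == "single")
    c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
  else c(1 - 1 / fl, 1 - 1 / fu)
  structure(list(icc = est, icc_model = model, icc_unit = unit,
                 ci_low = ci[1], ci_high = ci[2], conf = conf,
                 n = n, k = k, fvalue = Fv),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(%s, %s) = %.2f, %d%% CI [%.2f, %.2f] (n = %d, k = %d)\n",
              x$icc_model, x$icc_unit, x$icc, round(100 * x$conf),
              x$ci_low, x$ci_high, x$n, x$k))
  invisible(x)
}

#' Bland-Altman agreement analysis
#'
#' Per-subject differences between two measurement methods against their
#' means, with limits of agreement at mean +/- 1.96 SD of the differences.
#'
#' @param method_a,method_b Paired numeric vectors (same subjects, two
#'   methods); differences are `method_a - method_b`.
#' @return List of class `bland_altman`: `mean_diff`, `sd_diff`,
#'   `loa_low`, `loa_high`, and `points` (data frame `mean`, `diff`).
#' @examples
#' ba <- bland_altman(c(10, 12), c(8, 12))
#' ba$mean_diff  # 1
#' @export
bland_altman <- function(method_a, method_b) {
  stopifnot(length(method_a) == length(method_b), length(method_a) >= 2,
            !anyNA(method_a), !anyNA(method_b))
  d <- method_a - method_b
  m <- (method_a + method_b) / 2
  md <- mean(d)
  sdd <- stats::sd(d)
  structure(list(mean_diff = md, sd_diff = sdd,
                 loa_low = md - 1.96 * sdd, loa_high = md + 1.96 * sdd,
                 points = data.frame(mean = m, diff = d)),
            class = "bland_altman")
}

#' Plot a Bland-Altman analysis
#'
#' @param x A [bland_altman()] result.
#' @param main Plot title.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.bland_altman <- function(x, main = "Bland-Altman", ...) {
  graphics::plot(x$points$mean, x$points$diff, xlab = "Mean of methods",
                 ylab = "Difference (A - B)", main = main, pch = 19, ...)
  graphics::abline(h = x$mean_diff, lwd = 2)
  graphics::abline(h = c(x$loa_low, x$loa_high), col = "red", lty = 2)
  invisible(x)
}

#' Interpret reliability coefficients
#'
#' Labels an ICC as `poor` (<= 0.4), `fair-to-good` (0.4, 0.75\] or
#' `excellent` (> 0.75), and a Cronbach's alpha as `unacceptable`
#' (<= 0.5), `poor-to-good` (0.5, 0.9\] or `excellent` (> 0.9). Boundary
#' values fall in the lower band.
#'
#' @param icc_value ICC estimate in \[-1, 1\].
#' @param alpha_value Cronbach's alpha (<= 1).
#' @return Named character vector `c(icc_label=, alpha_label=)`.
#' @export
interpret_reliability <- function(icc_value, alpha_value) {
  stopifnot(icc_value >= -1, icc_value <= 1, alpha_value <= 1)
  icc_label <- if (icc_value <= 0.4) "poor"
               else if (icc_value <= 0.75) "fair-to-good" else "excellent"
  alpha_label <- if (alpha_value <= 0.5) "unacceptable"
                 else if (alpha_value <= 0.9) "poor-to-good" else "excellent"
  c(icc_label = icc_label, alpha_label = alpha_label)
}

#' Packaged two-method case-study results
#'
#' Paired manual-vs-sensor results for seven volunteers across all six SFT
#' items, in long format, as shipped with the package. This is the fixture
#' the agreement report reproduces.
#'
#' @return Data frame with columns `subject_id`, `test_code`, `method`
#'   (`manual` or `sensor`), `value`.
#' @export
case_study_results <- function() {
  p <- system.file("extdata", "case_study_paired.csv", package = "msft",
                   mustWork = TRUE)
  utils::read.csv(p, stringsAsFactors = FALSE)
}

# long paired results -> named list of n x 2 matrices (manual, sensor)
paired_matrices <- function(pairs) {
  need <- c("subject_id", "test_code", "method", "value")
  if (!all(need %in% names(pairs)))
    stop("paired results need columns ", paste(need, collapse = ", "),
         call. = FALSE)
  out <- list()
  for (code in unique(pairs$test_code)) {
    sub <- pairs[pairs$test_code == code, ]
    wide <- tryCatch(
      stats::reshape(sub[c("subject_id", "method", "value")],
                     idvar = "subject_id", timevar = "method",
                     direction = "wide"),
      error = function(e) stop("data error for item ", code, ": ",
                               conditionMessage(e), call. = FALSE))
    for (m in c("manual", "sensor")) {
      col <- paste0("value.", m)
      if (!col %in% names(wide) || anyNA(wide[[col]])) {
        miss <- if (col %in% names(wide))
          wide$subject_id[is.na(wide[[col]])] else unique(sub$subject_id)
        stop(sprintf("data error: item %s missing %s value for subject(s) %s",
                     code, m, paste(miss, collapse = ", ")), call. = FALSE)
      }
    }
    X <- cbind(manual = wide$value.manual, sensor = wide$value.sensor)
    rownames(X) <- wide$subject_id
    out[[code]] <- X
  }
  out
}

#' Per-item method-agreement report
#'
#' For each SFT item in a long-format paired-results table, computes the
#' ICC (default two-way consistency, average measures) with its 95%
#' confidence interval, Cronbach's alpha, and the interpretation labels of
#' [interpret_reliability()]. With the packaged [case_study_results()]
#' fixture this reproduces the published agreement table of the
#' seven-volunteer validation study.
#'
#' @param pairs Long data frame (`subject_id`, `test_code`, `method`,
#'   `value`); defaults to the packaged case study. Every subject must have
#'   both methods for every item it appears in.
#' @param icc_model,icc_unit ICC form, see [icc()].
#' @param conf Confidence level.
#' @return Data frame of class `agreement_report`, one row per item:
#'   `test_code`, `n`, `icc`, `ci_low`, `ci_high`, `cronbach_alpha`,
#'   `icc_label`, `alpha_label`, plus attributes `icc_model`/`icc_unit`.
#' @examples
#' rep <- agreement_report()
#' round(rep$cronbach_alpha, 2)
#' @export
agreement_report <- function(pairs = case_study_results(),
                             icc_model = "twoway_consistency",
                             icc_unit = "average", conf = 0.95) {
  mats <- paired_matrices(pairs)
  order_codes <- intersect(sft_items()$code, names(mats))
  mats <- mats[c(order_codes, setdiff(names(mats), order_codes))]
  rows <- lapply(names(mats), function(code) {
    X <- mats[[code]]
    ic <- icc(X, model = icc_model, unit = icc_unit, conf = conf)
    a <- cronbach_alpha(X)
    lab <- interpret_reliability(max(-1, min(1, ic$icc)), a)
    data.frame(test_code = code, n = nrow(X), icc = ic$icc,
               ci_low = ic$ci_low, ci_high = ic$ci_high,
               cronbach_alpha = a, icc_label = unname(lab["icc_label"]),
               alpha_label = unname(lab["alpha_label"]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "icc_model") <- icc_model
  attr(out, "icc_unit") <- icc_unit
  attr(out, "conf") <- conf
  class(out) <- c("agreement_report", "data.frame")
  out
}

#' @export
print.agreement_report <- function(x, digits = 2, ...) {
  cat(sprintf("Method-agreement report (ICC: %s, %s measures; %d%% CI)\n",
              attr(x, "icc_model"), attr(x, "icc_unit"),
              round(100 * attr(x, "conf"))))
  y <- as.data.frame(x)
  for (col in c("icc", "ci_low", "ci_high", "cronbach_alpha"))
    y[[col]] <- round(y[[col]], digits)
  print(y, row.names = FALSE)
  invisible(x)
}
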