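.norms_env <- new.env(parent = emptyenv())

#' Normative reference table for the Senior Fitness Test
#'
#' Mean and standard deviation per item and 10-year age band (60-69,
#' 70-79, 80-89) from the Rikli-Jones reference sample, sex-pooled.
#' Shipped as a plain CSV so alternative tables (e.g. sex-specific) can be
#' dropped in.
#'
#' @param path Optional path to an alternative norms CSV with columns
#'   `test_code,age_band,mean,sd`.
#' @return Data frame with 18 rows and those four columns.
#' @export
sft_norms <- function(path = NULL) {
  if (is.null(path)) {
    if (is.null(.norms_env$norms)) {
      p <- system.file("extdata", "sft_norms.csv", package = "msft",
                       mustWork = TRUE)
      .norms_env$norms <- utils::read.csv(p, stringsAsFactors = FALSE)
    }
    return(.norms_env$norms)
  }
  utils::read.csv(path, stringsAsFactors = FALSE)
}

norm_age_band <- function(age) {
  if (age < 70) "60-69" else if (age < 80) "70-79" else "80-89"
}

#' Look up the normative entry for an item and age
#'
#' Ages between 60 and 89 select their exact band; ages outside clamp to
#' the nearest band and the result is flagged (`clamped_age = TRUE`) so
#' reports disclose the extrapolation — the instrument is routinely applied
#' to adults somewhat younger than the reference sample.
#'
#' @param test_code One of the six SFT item codes (see [sft_items()]).
#' @param age Age in years, in \[18, 110\].
#' @return List with `test_code`, `age_band`, `mean`, `sd`, `clamped_age`.
#' @examples
#' lookup_norm("chair_stand", 65)  # mean 14.0, sd 2.4
#' @export
lookup_norm <- function(test_code, age) {
  nm <- sft_norms()
  if (!test_code %in% nm$test_code)
    stop("unknown test_code: ", test_code, call. = FALSE)
  if (!is.finite(age) || age < 18 || age > 110)
    stop("age must be in [18, 110]", call. = FALSE)
  clamped <- age < 60 || age > 89
  band <- norm_age_band(min(max(age, 60), 89))
  row <- nm[nm$test_code == test_code & nm$age_band == band, ]
  list(test_code = test_code, age_band = band,
       mean = row$mean, sd = row$sd, clamped_age = clamped)
}

#' Classify a result against the normative band
#'
#' Computes the z-score of a result relative to the age-band reference and
#' labels it `below` / `within` / `above`, where "within" is |z| <= width
#' (default one standard deviation). For the up-and-go item a lower time is
#' better, so the classification carries a direction note; the z sign is
#' reported as computed.
#'
#' @param test_code SFT item code.
#' @param age Age in years.
#' @param value Result in the item's unit.
#' @param width Half-width of the "within" band in SD units (default 1).
#' @return List of class `norm_classification`: `test_code`, `band_used`,
#'   `z`, `label`, `clamped_age`, `direction` (`"higher_is_better"` or
#'   `"lower_is_better"`).
#' @examples
#' classify_norm("chair_stand", 65, 10)  # z = -1.67, below
#' @export
classify_norm <- function(test_code, age, value, width = 1) {
  entry <- lookup_norm(test_code, age)
  stopifnot(is.finite(value), width > 0)
  z <- (value - entry$mean) / entry$sd
  label <- if (abs(z) <= width) "within" else if (z < 0) "below" else "above"
  structure(list(test_code = test_code, band_used = entry$age_band, z = z,
                 label = label, clamped_age = entry$clamped_age,
                 direction = if (test_code == "up_and_go")
                   "lower_is_better" else "higher_is_better"),
            class = "norm_classification")
}

#' @export
print.norm_classification <- function(x, ...) {
  cat(sprintf("%s (band %s%s): z = %.2f -> %s%s\n", x$test_code, x$band_used,
              if (x$clamped_age) ", age clamped" else "", x$z, x$label,
              if (x$direction == "lower_is_better") " (lower is better)" else ""))
  invisible(x)
}
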