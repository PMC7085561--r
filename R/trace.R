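#' @importFrom stats median qf rnorm runif sd var
#' @importFrom utils read.csv write.csv
NULL

# Standard gravity used throughout (Android reports fused gravity in m/s^2).
GRAVITY_MS2 <- 9.81

# Physical-plausibility band for |g|: +/- ~10% around standard gravity.
# Out-of-band samples are flagged in trace metadata, never rejected: the
# gravity "sensor" is a software fusion of accelerometer + gyroscope and
# transiently drifts outside the band during fast movement.
NORM_BAND_MS2 <- c(8.8, 10.8)

#' Gravity-sensor trace
#'
#' Container for a time series of gravity-vector samples as produced by a
#' smartphone gravity sensor mounted on the leg or forearm during a Senior
#' Fitness Test item. Timestamps are seconds since trace start and must be
#' strictly increasing; components are in m/s^2 in device coordinates.
#'
#' Samples whose vector norm falls outside the plausibility band
#' \[8.8, 10.8\] m/s^2 are recorded in `meta$norm_warnings` (sample indices)
#' but kept: transient out-of-band norms are expected from fused sensors.
#'
#' @param t Numeric vector of timestamps (s), finite, non-negative, strictly
#'   increasing.
#' @param x,y,z Numeric vectors of gravity components (m/s^2), same length
#'   as `t`.
#' @param sample_rate_hz Nominal sampling rate (Hz). If `NULL`, inferred
#'   from the median timestamp spacing. Algorithms use actual timestamps;
#'   the rate is metadata only.
#' @param meta Named list of free-form metadata (device, test item, subject).
#' @return An object of class `gravity_trace`: a list with elements
#'   `samples` (data frame with columns `t`, `x`, `y`, `z`),
#'   `sample_rate_hz` and `meta`.
#' @examples
#' tr <- gravity_trace(t = c(0, 0.02, 0.04), x = 0, y = c(0, -4.9, -9.8),
#'                     z = c(9.81, 8.498, 0.443))
#' trace_duration(tr)
#' @export
gravity_trace <- function(t, x, y, z, sample_rate_hz = NULL, meta = list()) {
  n <- length(t)
  if (n == 0L) stop("no samples", call. = FALSE)
  x <- rep_len(as.numeric(x), n)
  y <- rep_len(as.numeric(y), n)
  z <- rep_len(as.numeric(z), n)
  t <- as.numeric(t)
  if (!all(is.finite(t)) || any(t < 0))
    stop("timestamps must be finite and non-negative", call. = FALSE)
  if (n > 1L && any(diff(t) <= 0))
    stop("ordering error: timestamps must be strictly increasing", call. = FALSE)
  if (!all(is.finite(c(x, y, z))))
    stop("gravity components must be finite", call. = FALSE)
  if (is.null(sample_rate_hz)) {
    sample_rate_hz <- if (n > 1L) 1 / stats::median(diff(t)) else NA_real_
  }
  if (!is.na(sample_rate_hz) && sample_rate_hz <= 0)
    stop("sample_rate_hz must be positive", call. = FALSE)
  nrm <- sqrt(x^2 + y^2 + z^2)
  bad <- which(nrm < NORM_BAND_MS2[1] | nrm > NORM_BAND_MS2[2])
  if (length(bad)) meta$norm_warnings <- bad
  structure(
    list(samples = data.frame(t = t, x = x, y = y, z = z),
         sample_rate_hz = sample_rate_hz, meta = meta),
    class = "gravity_trace"
  )
}

#' @export
print.gravity_trace <- function(x, ...) {
  s <- x$samples
  cat(sprintf("<gravity_trace> %d samples, %.3f s, ~%.1f Hz\n",
              nrow(s), trace_duration(x),
              if (is.na(x$sample_rate_hz)) NA_real_ else x$sample_rate_hz))
  if (length(x$meta$norm_warnings))
    cat(sprintf("  %d sample(s) outside |g| band [%.1f, %.1f] m/s^2\n",
                length(x$meta$norm_warnings), NORM_BAND_MS2[1], NORM_BAND_MS2[2]))
  invisible(x)
}

#' Trace duration in seconds
#' @param trace A [gravity_trace()].
#' @return `t_last - t_first` (s).
#' @export
trace_duration <- function(trace) {
  stopifnot(inherits(trace, "gravity_trace"))
  tt <- trace$samples$t
  tt[length(tt)] - tt[1]
}

#' Read a gravity trace from CSV
#'
#' The canonical dialect is comma-separated UTF-8 with a header row naming
#' columns `t,x,y,z` (seconds, then m/s^2). Lines starting with `#` before
#' the header carry `key=value` metadata and are restored into `meta`.
#' Column names can be remapped for devices with different axis conventions.
#'
#' @param path Path to a trace CSV file.
#' @param columns Named character vector mapping canonical names to file
#'   column names, e.g. `c(t = "time", y = "ay")`.
#' @return A [gravity_trace()]; out-of-band vector norms are flagged in
#'   `meta$norm_warnings`.
#' @export
read_trace <- function(path, columns = c(t = "t", x = "x", y = "y", z = "z")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  is_meta <- grepl("^#", lines)
  meta <- list()
  for (ml in sub("^#\\s*", "", lines[is_meta])) {
    kv <- regmatches(ml, regexpr("=", ml), invert = TRUE)[[1]]
    if (length(kv) == 2L) meta[[trimws(kv[1])]] <- trimws(kv[2])
  }
  body <- lines[!is_meta & nzchar(trimws(lines))]
  if (length(body) < 1L) stop("no samples", call. = FALSE)
  header <- strsplit(body[1], ",")[[1]]
  header <- trimws(header)
  cmap <- c(t = "t", x = "x", y = "y", z = "z")
  cmap[names(columns)] <- columns
  idx <- match(cmap, header)
  if (anyNA(idx))
    stop("missing column(s): ", paste(cmap[is.na(idx)], collapse = ", "),
         call. = FALSE)
  if (length(body) < 2L) stop("no samples", call. = FALSE)
  rows <- strsplit(body[-1], ",")
  line_no <- which(!is_meta)[-1]  # file line numbers of data rows
  vals <- matrix(NA_real_, nrow = length(rows), ncol = 4L)
  for (i in seq_along(rows)) {
    f <- trimws(rows[[i]])
    if (length(f) < max(idx))
      stop(sprintf("parse error at line %d: expected %d fields, got %d",
                   line_no[i], length(header), length(f)), call. = FALSE)
    v <- suppressWarnings(as.numeric(f[idx]))
    if (anyNA(v))
      stop(sprintf("parse error at line %d: non-numeric value", line_no[i]),
           call. = FALSE)
    vals[i, ] <- v
  }
  gravity_trace(t = vals[, 1], x = vals[, 2], y = vals[, 3], z = vals[, 4],
                meta = meta)
}

#' Write a gravity trace to CSV
#'
#' Inverse of [read_trace()]: components are written with six decimal
#' places, scalar metadata entries as leading `#key=value` comment lines.
#'
#' @param trace A non-empty [gravity_trace()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "gravity_trace"))
  s <- trace$samples
  if (nrow(s) == 0L) stop("no samples", call. = FALSE)
  con <- tryCatch(suppressWarnings(file(path, open = "wt")),
                  error = function(e)
    stop("cannot write to ", path, ": ", conditionMessage(e), call. = FALSE))
  on.exit(close(con))
  meta <- trace$meta
  meta$norm_warnings <- NULL  # recomputed on read
  for (k in names(meta)) {
    v <- meta[[k]]
    if (is.atomic(v) && length(v) == 1L)
      writeLines(sprintf("#%s=%s", k, as.character(v)), con)
  }
  writeLines("t,x,y,z", con)
  writeLines(sprintf("%.6f,%.6f,%.6f,%.6f", s$t, s$x, s$y, s$z), con)
  invisible(path)
}

#' Smooth a trace with a centred moving average
#'
#' Applies a centred moving average of `window` samples to each axis,
#' preserving length; near the edges the window shrinks symmetrically.
#' Used as the detector pre-filter.
#'
#' @param trace A [gravity_trace()].
#' @param window Odd positive integer window length in samples; `1` is the
#'   identity.
#' @return A smoothed [gravity_trace()].
#' @export
smooth_trace <- function(trace, window) {
  stopifnot(inherits(trace, "gravity_trace"))
  if (length(window) != 1L || !is.finite(window) || window < 1 ||
      window != as.integer(window) || as.integer(window) %% 2L == 0L)
    stop("window must be a positive odd integer", call. = FALSE)
  if (window == 1L) return(trace)
  s <- trace$samples
  gravity_trace(t = s$t,
                x = running_mean(s$x, window),
                y = running_mean(s$y, window),
                z = running_mean(s$z, window),
                sample_rate_hz = trace$sample_rate_hz,
                meta = trace$meta)
}

# centred moving average, length-preserving; edge windows shrink
# symmetrically (stay centred and odd), which conserves the full-trace sum
# exactly when the outermost 2h samples on each side are constant
running_mean <- function(v, w) {
  n <- length(v)
  h <- (w - 1L) %/% 2L
  cs <- cumsum(c(0, v))
  i <- seq_len(n)
  hw <- pmin(h, i - 1L, n - i)
  lo <- i - hw
  hi <- i + hw
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}
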