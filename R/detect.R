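#' Repetition-detector configuration
#'
#' A two-phase hysteresis state machine over the smoothed y gravity
#' channel: the machine rests in BASELINE, moves to ACTIVE when the active
#' predicate holds continuously for at least `min_phase_s`, and credits one
#' repetition when the baseline predicate then holds continuously for at
#' least `min_phase_s` (the repetition completes on the return to the
#' initial state). Predicates are one-sided or symmetric threshold tests:
#' `"lt"` (y below threshold), `"gt"` (y above), `"abs_lt"` (|y| below).
#' The two bands must not overlap, leaving a hysteresis gap in which no
#' oscillation can trigger a count.
#'
#' @param test_kind Optional item code the configuration is meant for.
#' @param active_enter,active_op Threshold (m/s^2) and predicate for
#'   entering the ACTIVE phase.
#' @param baseline_enter,baseline_op Threshold and predicate for returning
#'   to BASELINE.
#' @param min_phase_s Minimum continuous dwell (s) to accept a phase;
#'   debounces sample-level noise spikes.
#' @param smooth_window Odd moving-average window (samples) applied before
#'   detection.
#' @param max_duration_s Test time limit (s); samples after it are ignored.
#' @return A list of class `detector_config`.
#' @seealso [default_detector_config()], [count_repetitions()]
#' @export
detector_config <- function(test_kind = NULL, active_enter, active_op,
                            baseline_enter, baseline_op,
                            min_phase_s = 0.15, smooth_window = 5,
                            max_duration_s) {
  active_op <- match.arg(active_op, c("lt", "gt", "abs_lt"))
  baseline_op <- match.arg(baseline_op, c("lt", "gt", "abs_lt"))
  stopifnot(min_phase_s >= 0, max_duration_s > 0)
  if (bands_overlap(active_op, active_enter, baseline_op, baseline_enter))
    stop("active and baseline bands overlap: no hysteresis gap", call. = FALSE)
  structure(list(test_kind = test_kind,
                 active_enter = active_enter, active_op = active_op,
                 baseline_enter = baseline_enter, baseline_op = baseline_op,
                 min_phase_s = min_phase_s,
                 smooth_window = as.integer(smooth_window),
                 max_duration_s = max_duration_s),
            class = "detector_config")
}

# each predicate selects an open interval of y values
pred_interval <- function(op, thr) {
  switch(op,
         lt = c(-Inf, thr),
         gt = c(thr, Inf),
         abs_lt = c(-abs(thr), abs(thr)))
}

bands_overlap <- function(op_a, thr_a, op_b, thr_b) {
  a <- pred_interval(op_a, thr_a)
  b <- pred_interval(op_b, thr_b)
  max(a[1], b[1]) < min(a[2], b[2])
}

pred_apply <- function(y, op, thr) {
  switch(op, lt = y < thr, gt = y > thr, abs_lt = abs(y) < abs(thr))
}

#' Default detector configuration per test item
#'
#' Thresholds anchor to the items' datum values (phone vertical: y near
#' -9.8 m/s^2; arm curled past vertical: y above +7.5 m/s^2) with margins
#' so that noisy fused-sensor signals that approach but do not attain the
#' exact extremum still trigger:
#' \describe{
#'   \item{chair_stand}{baseline |y| < 2.0, active y < -8.0, limit 30 s.}
#'   \item{arm_curl}{baseline y < -5.0, active y > +7.5, limit 30 s.}
#'   \item{two_min_step}{baseline y < -8.0, active y > -2.0, limit 120 s.}
#' }
#' All use a 0.15 s dwell debounce and a 5-sample smoothing window.
#'
#' @param test_kind One of `"chair_stand"`, `"arm_curl"`, `"two_min_step"`.
#' @return A [detector_config()].
#' @export
default_detector_config <- function(test_kind) {
  test_kind <- match.arg(test_kind, SENSOR_KINDS)
  switch(test_kind,
    chair_stand = detector_config(test_kind, active_enter = -8.0,
                                  active_op = "lt", baseline_enter = 2.0,
                                  baseline_op = "abs_lt", max_duration_s = 30),
    arm_curl = detector_config(test_kind, active_enter = 7.5,
                               active_op = "gt", baseline_enter = -5.0,
                               baseline_op = "lt", max_duration_s = 30),
    two_min_step = detector_config(test_kind, active_enter = -2.0,
                                   active_op = "gt", baseline_enter = -8.0,
                                   baseline_op = "lt", max_duration_s = 120))
}

#' Count repetitions in a gravity trace
#'
#' Runs the hysteresis state machine of a [detector_config()] over the
#' smoothed y channel. The trace is first truncated to the configured time
#' limit (relative to its first timestamp). A phase change requires its
#' predicate to hold continuously for at least `min_phase_s`; a repetition
#' is credited at the timestamp of the first sample of the qualifying
#' return-to-baseline run. A trace that starts with the active predicate
#' already satisfied begins in the ACTIVE state.
#'
#' @param trace A non-empty [gravity_trace()].
#' @param config A [detector_config()].
#' @return A list of class `detection_result`: `reps` (count), `rep_times`
#'   (completion timestamps, s), `incomplete_final_phase` (`TRUE` if the
#'   trace ends mid-repetition) and `truncated_at_s` (time limit applied,
#'   or `NA` if the trace fit within it).
#' @examples
#' sim <- simulate_trace(sim_spec("arm_curl", n_reps = 5, noise_sd = 0.2,
#'                                seed = 7))
#' count_repetitions(sim$trace, default_detector_config("arm_curl"))$reps
#' @export
count_repetitions <- function(trace, config) {
  stopifnot(inherits(trace, "gravity_trace"), inherits(config, "detector_config"))
  s <- trace$samples
  rel <- s$t - s$t[1]
  keep <- rel <= config$max_duration_s + 1e-9
  truncated <- !all(keep)
  s <- s[keep, , drop = FALSE]
  y <- running_mean(s$y, config$smooth_window)
  tt <- s$t
  act <- pred_apply(y, config$active_op, config$active_enter)
  bas <- pred_apply(y, config$baseline_op, config$baseline_enter)

  runs_of <- function(p) {
    r <- rle(p)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    ok <- r$values & (tt[ends] - tt[starts] >= config$min_phase_s - 1e-9)
    cbind(start = starts[ok], end = ends[ok])
  }
  ra <- runs_of(act)
  rb <- runs_of(bas)
  ev <- rbind(if (nrow(ra)) cbind(ra, type = 1L),
              if (nrow(rb)) cbind(rb, type = 0L))
  state_active <- isTRUE(act[1])
  reps <- 0L
  rep_times <- numeric(0)
  if (!is.null(ev) && nrow(ev)) {
    ev <- ev[order(ev[, "start"]), , drop = FALSE]
    for (i in seq_len(nrow(ev))) {
      if (ev[i, "type"] == 1L && !state_active) {
        state_active <- TRUE
      } else if (ev[i, "type"] == 0L && state_active) {
        reps <- reps + 1L
        rep_times <- c(rep_times, tt[ev[i, "start"]])
        state_active <- FALSE
      }
    }
  }
  structure(list(reps = reps, rep_times = rep_times,
                 incomplete_final_phase = state_active,
                 truncated_at_s = if (truncated) config$max_duration_s else NA_real_),
            class = "detection_result")
}

#' @export
print.detection_result <- function(x, ...) {
  cat(sprintf("<detection_result> %d rep(s)%s%s\n", x$reps,
              if (x$incomplete_final_phase) ", final phase incomplete" else "",
              if (!is.na(x$truncated_at_s))
                sprintf(", truncated at %g s", x$truncated_at_s) else ""))
  invisible(x)
}

#' Stopwatch item timing
#'
#' Elapsed time per trial is rounded half-up to the nearest 0.1 s (the
#' protocol records to the nearest tenth); the fastest trial is returned.
#'
#' @param trials A list of `c(start_s, stop_s)` pairs, or a two-column
#'   matrix (start, stop), one row per trial.
#' @return Fastest rounded elapsed time (s).
#' @examples
#' stopwatch_time(list(c(0, 5.27), c(0, 5.61)))  # 5.3
#' @export
stopwatch_time <- function(trials) {
  if (is.matrix(trials)) trials <- asplit(trials, 1)
  if (!length(trials)) stop("at least one trial required", call. = FALSE)
  elapsed <- vapply(trials, function(tr) {
    if (length(tr) != 2L || !all(is.finite(tr)))
      stop("each trial must be a finite (start, stop) pair", call. = FALSE)
    if (tr[2] <= tr[1]) stop("stop time must exceed start time", call. = FALSE)
    tr[2] - tr[1]
  }, numeric(1))
  min(round_half_up(elapsed, 0.1))
}

# round half-up on a grid of `unit`; guards the x.x5 boundary against
# binary representation error
round_half_up <- function(x, unit) {
  floor(x / unit + 0.5 + sqrt(.Machine$double.eps)) * unit
}
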