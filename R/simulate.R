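SENSOR_KINDS <- c("chair_stand", "arm_curl", "two_min_step")

# Default full-cycle repetition periods (s), chosen so that the largest
# normative repetition count (60-69 band mean + 2 SD) completes inside the
# item's time limit: participants pace themselves to finish within the test.
DEFAULT_REP_PERIOD_S <- c(chair_stand = 1.4, arm_curl = 0.95, two_min_step = 0.9)

# Arm-curl active plateau: forearm slightly past vertical so the +7.5 m/s^2
# datum is crossed with margin.
ARM_CURL_ACTIVE_Y <- 8.5

#' Simulation specification for a gravity trace
#'
#' Describes one simulated execution of a sensor-based SFT item. The
#' waveform is a two-plateau cycle of the phone's pitch angle in the y-z
#' plane with raised-cosine ramps; the y gravity component alternates
#' between the item's baseline and active plateau:
#' \describe{
#'   \item{chair_stand}{sitting, phone flat: y near 0; standing, phone
#'     vertical upside-down: y near -9.8 m/s^2.}
#'   \item{arm_curl}{arm extended, phone upside-down: y near -9.8; fist
#'     curled past vertical: y near +8.5 m/s^2.}
#'   \item{two_min_step}{standing: y near -9.8; knee raised with thigh
#'     horizontal: y near 0 m/s^2.}
#' }
#' The x component carries only noise; z is the sign-consistent complement
#' so that the noiseless vector norm is exactly 9.81 m/s^2. Gaussian noise
#' of `noise_sd` is added per axis after norm construction.
#'
#' @param test_kind One of `"chair_stand"`, `"arm_curl"`, `"two_min_step"`.
#' @param n_reps Positive integer number of repetitions to simulate.
#' @param rep_period_s Full-cycle repetition period (s). Defaults per item
#'   to 1.4 / 0.95 / 0.9 s so normative counts fit the item's time limit.
#' @param transition_frac Fraction of the period spent ramping (0-0.9).
#' @param sample_rate_hz Sampling rate (Hz).
#' @param noise_sd Gaussian noise standard deviation per axis (m/s^2).
#' @param tilt_deg Baseline mounting tilt in the y-z plane (-20..20 deg).
#' @param lead_s Lead-in and lead-out baseline plateau duration (s).
#' @param seed Integer seed; the same spec always yields the same trace.
#'   `NULL` uses the current RNG state.
#' @return A list of class `sim_spec`.
#' @seealso [simulate_trace()], [simulate_battery()]
#' @export
sim_spec <- function(test_kind, n_reps, rep_period_s = NULL,
                     transition_frac = 0.3, sample_rate_hz = 50,
                     noise_sd = 0.2, tilt_deg = 0, lead_s = 1.5,
                     seed = NULL) {
  test_kind <- match.arg(test_kind, SENSOR_KINDS)
  if (is.null(rep_period_s)) rep_period_s <- DEFAULT_REP_PERIOD_S[[test_kind]]
  stopifnot(n_reps >= 1, n_reps == as.integer(n_reps),
            rep_period_s > 0, transition_frac >= 0, transition_frac <= 0.9,
            sample_rate_hz > 0, noise_sd >= 0,
            tilt_deg >= -20, tilt_deg <= 20, lead_s >= 0)
  structure(list(test_kind = test_kind, n_reps = as.integer(n_reps),
                 rep_period_s = rep_period_s, transition_frac = transition_frac,
                 sample_rate_hz = sample_rate_hz, noise_sd = noise_sd,
                 tilt_deg = tilt_deg, lead_s = lead_s, seed = seed),
            class = "sim_spec")
}

# run expr with the RNG seeded locally; global RNG state is untouched
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()) else
    suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  set.seed(seed)
  expr
}

#' Simulate a gravity trace with known ground truth
#'
#' Generates a [gravity_trace()] for one SFT item execution together with
#' the true repetition count and per-repetition boundary times, for use as
#' seeded test fixtures with exact ground truth.
#'
#' @param spec A [sim_spec()].
#' @return A list of class `sim_result` with elements `trace`
#'   ([gravity_trace()]), `true_reps` (integer) and `rep_boundaries`
#'   (data frame with columns `start_s`, `mid_s`, `end_s`, one row per
#'   repetition).
#' @examples
#' sim <- simulate_trace(sim_spec("chair_stand", n_reps = 12, noise_sd = 0))
#' sim$true_reps
#' range(sqrt(rowSums(sim$trace$samples[, c("x", "y", "z")]^2)))
#' @export
simulate_trace <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  with_local_seed(spec$seed, {
    g <- GRAVITY_MS2
    tilt <- spec$tilt_deg * pi / 180
    # pitch angle phi from horizontal: y = -g sin(phi), z = g cos(phi)
    ang <- switch(spec$test_kind,
      chair_stand  = c(base = tilt, active = pi / 2),
      two_min_step = c(base = pi / 2 - tilt, active = 0),
      arm_curl     = c(base = pi / 2 - tilt, active = -asin(ARM_CURL_ACTIVE_Y / g)))
    T_ <- spec$rep_period_s
    r <- spec$transition_frac * T_ / 2       # ramp duration
    dur <- 2 * spec$lead_s + spec$n_reps * T_
    tt <- seq(0, dur, by = 1 / spec$sample_rate_hz)
    u <- tt - spec$lead_s                     # time since first rep start
    inrep <- u >= 0 & u < spec$n_reps * T_
    ph <- ifelse(inrep, u %% T_, NA_real_)    # phase within the cycle
    frac <- numeric(length(tt))               # 0 = baseline, 1 = active
    frac[inrep & ph < r] <- ramp01(ph[inrep & ph < r] / r)
    frac[inrep & ph >= r & ph < T_ / 2] <- 1
    dn <- inrep & ph >= T_ / 2 & ph < T_ / 2 + r
    frac[dn] <- 1 - ramp01((ph[dn] - T_ / 2) / r)
    phi <- ang[["base"]] + (ang[["active"]] - ang[["base"]]) * frac
    y <- -g * sin(phi)
    z <- g * cos(phi)
    x <- numeric(length(tt))
    if (spec$noise_sd > 0) {
      x <- x + rnorm(length(tt), 0, spec$noise_sd)
      y <- y + rnorm(length(tt), 0, spec$noise_sd)
      z <- z + rnorm(length(tt), 0, spec$noise_sd)
    }
    starts <- spec$lead_s + (seq_len(spec$n_reps) - 1) * T_
    trace <- gravity_trace(tt, x, y, z, sample_rate_hz = spec$sample_rate_hz,
                           meta = list(test_item = spec$test_kind,
                                       simulated = "true"))
    structure(list(trace = trace, true_reps = spec$n_reps,
                   rep_boundaries = data.frame(start_s = starts,
                                               mid_s = starts + T_ / 2,
                                               end_s = starts + T_)),
              class = "sim_result")
  })
}

# raised-cosine ramp from 0 to 1 over s in [0, 1]
ramp01 <- function(s) (1 - cos(pi * s)) / 2

#' Simulate one default trace per sensor-based item
#'
#' Draws a repetition count for each sensor-based item uniformly from the
#' 60-69-year normative band (mean +/- 2 SD, rounded to integers) and
#' simulates a default-parameter trace for it, giving a seeded, labelled
#' mini-battery of fixtures.
#'
#' @param seed Integer seed controlling both the drawn counts and the
#'   traces.
#' @return Named list (one entry per sensor kind) of `sim_result` objects.
#' @export
simulate_battery <- function(seed) {
  with_local_seed(seed, {
    out <- list()
    for (kind in SENSOR_KINDS) {
      nm <- lookup_norm(kind, 65)
      lo <- round(nm$mean - 2 * nm$sd)
      hi <- round(nm$mean + 2 * nm$sd)
      n <- sample(seq.int(lo, hi), 1L)
      sub_seed <- sample.int(.Machine$integer.max, 1L)
      out[[kind]] <- simulate_trace(sim_spec(kind, n_reps = n, seed = sub_seed))
    }
    out
  })
}
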