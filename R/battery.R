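#' The six Senior Fitness Test items
#'
#' Closed registry of the battery: three sensor-counted items, two
#' manually measured distances and one stopwatch item.
#'
#' @return Data frame with columns `code`, `measure`, `unit` (`count`,
#'   `cm` or `s`), `mode` (`sensor`, `manual`, `stopwatch`),
#'   `default_duration_s` and `equipment_note`.
#' @export
sft_items <- function() {
  data.frame(
    code = c("chair_stand", "arm_curl", "two_min_step",
             "sit_reach", "back_scratch", "up_and_go"),
    measure = c("lower-limb strength", "upper-limb strength",
                "aerobic endurance", "lower-body flexibility",
                "upper-limb flexibility", "agility and dynamic balance"),
    unit = c("count", "count", "count", "cm", "cm", "s"),
    mode = c("sensor", "sensor", "sensor", "manual", "manual", "stopwatch"),
    default_duration_s = c(30, 30, 120, NA, NA, NA),
    equipment_note = c("standard chair, arms crossed",
                       "weight 5 lb (2.27 kg) women / 8 lb (3.63 kg) men",
                       "knee raised to mid iliac crest-patella height",
                       "chair edge, one leg extended", "both hands behind back",
                       "8 ft (2.45 m) out-and-back course"),
    stringsAsFactors = FALSE)
}

item_row <- function(test_code) {
  it <- sft_items()
  row <- it[it$code == test_code, ]
  if (nrow(row) != 1L) stop("unknown test_code: ", test_code, call. = FALSE)
  row
}

# manual-entry sanity bands: signed reach distances and plausible times
CM_BAND <- c(-60, 60)
TIME_BAND_S <- c(0, 120)

validate_item_value <- function(test_code, value) {
  row <- item_row(test_code)
  if (length(value) != 1L || !is.finite(value))
    stop("value must be a single finite number", call. = FALSE)
  switch(row$unit,
    count = if (value < 0 || value != as.integer(value))
      stop("count for ", test_code, " must be an integer >= 0", call. = FALSE),
    cm = if (value < CM_BAND[1] || value > CM_BAND[2])
      stop(sprintf("value %g cm for %s outside sanity band [%g, %g]",
                   value, test_code, CM_BAND[1], CM_BAND[2]), call. = FALSE),
    s = if (value <= TIME_BAND_S[1] || value > TIME_BAND_S[2])
      stop(sprintf("time %g s for %s outside (0, %g] s",
                   value, test_code, TIME_BAND_S[2]), call. = FALSE))
  invisible(value)
}

item_result <- function(test_code, value, source, trace_ref = NULL) {
  validate_item_value(test_code, value)
  structure(list(test_code = test_code, value = value, source = source,
                 trace_ref = trace_ref),
            class = "item_result")
}

#' Score a sensor-based item from a gravity trace
#'
#' Runs the repetition detector on the trace and wraps the count as an
#' item result.
#'
#' @param test_code A sensor-mode item code (`chair_stand`, `arm_curl`,
#'   `two_min_step`).
#' @param trace A [gravity_trace()].
#' @param config Optional [detector_config()]; the item default otherwise.
#' @return An `item_result` with `source = "detector"` and the detection
#'   detail in attribute `"detection"`.
#' @export
run_sensor_item <- function(test_code, trace, config = NULL) {
  row <- item_row(test_code)
  if (row$mode != "sensor")
    stop(test_code, " is a ", row$mode, " item, not a sensor item",
         call. = FALSE)
  if (is.null(config)) config <- default_detector_config(test_code)
  det <- count_repetitions(trace, config)
  res <- item_result(test_code, det$reps, source = "detector",
                     trace_ref = trace$meta$trace_ref)
  attr(res, "detection") <- det
  res
}

#' Enter a manually measured item result
#'
#' For the two distance items (signed centimetres: negative means the
#' target was not reached) and the stopwatch item. Values outside the
#' per-unit sanity band are rejected with the band stated.
#'
#' @param test_code A manual- or stopwatch-mode item code.
#' @param value Result in the item's unit.
#' @return An `item_result` with `source = "manual"`.
#' @examples
#' enter_manual_item("back_scratch", -3.5)
#' @export
enter_manual_item <- function(test_code, value) {
  row <- item_row(test_code)
  if (row$mode == "sensor")
    stop(test_code, " is a sensor item; use run_sensor_item()", call. = FALSE)
  item_result(test_code, value, source = "manual")
}

#' Summarise a test session against the normative bands
#'
#' Classifies each recorded item result relative to the person's age band
#' and reports battery completion. Partially completed sessions are valid:
#' missing items are listed, not errors.
#'
#' @param results List of `item_result` objects (at most one per item).
#' @param person A [person()] record (supplies birth date for the age).
#' @param session_date Date of the session (default today).
#' @return A list of class `session_report`: `person_id`, `age`, `items`
#'   (data frame with value, z, label per completed item),
#'   `completion` (fraction of 6) and `missing` (item codes).
#' @export
session_summary <- function(results, person, session_date = Sys.Date()) {
  stopifnot(length(results) >= 1L, inherits(person, "msft_person"))
  codes <- vapply(results, function(r) r$test_code, character(1))
  if (anyDuplicated(codes))
    stop("duplicate item result: ", codes[duplicated(codes)][1], call. = FALSE)
  age <- person_age(person, session_date)
  rows <- lapply(results, function(r) {
    cl <- classify_norm(r$test_code, age, r$value)
    data.frame(test_code = r$test_code, value = r$value, source = r$source,
               band_used = cl$band_used, z = cl$z, label = cl$label,
               clamped_age = cl$clamped_age, stringsAsFactors = FALSE)
  })
  items <- do.call(rbind, rows)
  all_codes <- sft_items()$code
  structure(list(person_id = person$person_id, age = age,
                 session_date = as.character(session_date), items = items,
                 completion = length(codes) / length(all_codes),
                 missing = setdiff(all_codes, codes)),
            class = "session_report")
}

#' @export
print.session_report <- function(x, ...) {
  cat(sprintf("SFT session for %s (age %d): %d/6 items\n",
              x$person_id, x$age, nrow(x$items)))
  print(x$items, row.names = FALSE)
  if (length(x$missing)) cat("missing:", paste(x$missing, collapse = ", "), "\n")
  invisible(x)
}
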