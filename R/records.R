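#' Person record
#'
#' Profile entry of the record store: identifier, birth date (used to
#' derive the age at each session date, so ages never go stale), sex
#' (used only for equipment annotation — the packaged norms are
#' sex-pooled), optional contact text and photo path.
#'
#' @param person_id Unique identifier string.
#' @param birth_date A `Date` (or parseable string), in the past.
#' @param sex `"female"` or `"male"`.
#' @param contact,photo_ref Optional strings.
#' @return A list of class `msft_person`.
#' @export
person <- function(person_id, birth_date, sex, contact = NULL,
                   photo_ref = NULL) {
  stopifnot(is.character(person_id), nzchar(person_id))
  birth_date <- as.Date(birth_date)
  if (is.na(birth_date) || birth_date >= Sys.Date())
    stop("birth_date must be a past date", call. = FALSE)
  sex <- match.arg(sex, c("female", "male"))
  structure(list(person_id = person_id, birth_date = as.character(birth_date),
                 sex = sex, contact = contact, photo_ref = photo_ref),
            class = "msft_person")
}

# whole years between birth date and a reference date
person_age <- function(person, at_date = Sys.Date()) {
  b <- as.POSIXlt(as.Date(person$birth_date))
  a <- as.POSIXlt(as.Date(at_date))
  age <- a$year - b$year
  if (a$mon < b$mon || (a$mon == b$mon && a$mday < b$mday)) age <- age - 1L
  as.integer(age)
}

#' Session record
#'
#' One test session of a person: a date and up to one [item
#' result][enter_manual_item] per battery item. Partially completed
#' sessions are first-class and can be resumed.
#'
#' @param session_id Unique identifier string.
#' @param person_id Identifier of an existing [person()].
#' @param date Session date.
#' @param item_results List of `item_result` objects.
#' @param completed Logical.
#' @return A list of class `msft_session`.
#' @export
session_record <- function(session_id, person_id, date,
                           item_results = list(), completed = FALSE) {
  stopifnot(is.character(session_id), nzchar(session_id),
            is.character(person_id), nzchar(person_id))
  codes <- vapply(item_results, function(r) r$test_code, character(1))
  if (anyDuplicated(codes))
    stop("at most one result per test item per session", call. = FALSE)
  structure(list(session_id = session_id, person_id = person_id,
                 date = as.character(as.Date(date)),
                 item_results = item_results, completed = isTRUE(completed)),
            class = "msft_session")
}

#' Sensor buffer record
#'
#' Pointer from a session and test item to the trace CSV captured during
#' it; the raw signal is kept on disk, not inside the store document.
#'
#' @param session_id Identifier of an existing session.
#' @param test_code Sensor item code.
#' @param trace_ref Path to the trace CSV.
#' @return A list of class `msft_buffer`.
#' @export
sensor_buffer <- function(session_id, test_code, trace_ref) {
  item_row(test_code)
  structure(list(session_id = session_id, test_code = test_code,
                 trace_ref = trace_ref),
            class = "msft_buffer")
}

#' Open (or create) a file-backed record store
#'
#' A single-file JSON document store holding persons, sessions and sensor
#' buffers. The file is human-diffable, versioned via a `schema_version`
#' field, and requires no network or service: the store works fully
#' offline and survives process restarts.
#'
#' @param path Path of the store JSON file; created empty if absent.
#' @return A handle of class `msft_store`.
#' @export
open_store <- function(path) {
  if (!file.exists(path)) {
    doc <- list(schema_version = 1L, persons = list(), sessions = list(),
                buffers = list())
    write_store_doc(doc, path)
  }
  structure(list(path = path), class = "msft_store")
}

read_store_doc <- function(store) {
  doc <- jsonlite::read_json(store$path, simplifyVector = FALSE)
  if (is.null(doc$schema_version))
    stop("not a record store: ", store$path, call. = FALSE)
  doc
}

write_store_doc <- function(doc, path) {
  jsonlite::write_json(doc, path, auto_unbox = TRUE, null = "null",
                       pretty = TRUE, digits = NA)
}

#' Insert or update an entity in the store
#'
#' Idempotent upsert keyed by the entity's identifier. Referential
#' integrity is enforced: sessions must reference an existing person,
#' buffers an existing session.
#'
#' @param store An [open_store()] handle.
#' @param entity A [person()], [session_record()] or [sensor_buffer()].
#' @return The stored id, invisibly.
#' @export
store_upsert <- function(store, entity) {
  stopifnot(inherits(store, "msft_store"))
  doc <- read_store_doc(store)
  if (inherits(entity, "msft_person")) {
    doc$persons[[entity$person_id]] <- unclass(entity)
    id <- entity$person_id
  } else if (inherits(entity, "msft_session")) {
    if (is.null(doc$persons[[entity$person_id]]))
      stop("integrity error: unknown person_id ", entity$person_id,
           call. = FALSE)
    e <- unclass(entity)
    e$item_results <- lapply(entity$item_results, unclass)
    doc$sessions[[entity$session_id]] <- e
    id <- entity$session_id
  } else if (inherits(entity, "msft_buffer")) {
    if (is.null(doc$sessions[[entity$session_id]]))
      stop("integrity error: unknown session_id ", entity$session_id,
           call. = FALSE)
    key <- paste(entity$session_id, entity$test_code, sep = "/")
    doc$buffers[[key]] <- unclass(entity)
    id <- key
  } else stop("unknown entity type", call. = FALSE)
  write_store_doc(doc, store$path)
  invisible(id)
}

#' Fetch one entity from the store
#'
#' @param store An [open_store()] handle.
#' @param kind `"person"`, `"session"` or `"buffer"`.
#' @param id The entity id (for buffers, `"<session_id>/<test_code>"`).
#' @return The stored entity as a list, or an error if absent.
#' @export
store_get <- function(store, kind, id) {
  doc <- read_store_doc(store)
  tab <- switch(match.arg(kind, c("person", "session", "buffer")),
                person = doc$persons, session = doc$sessions,
                buffer = doc$buffers)
  if (is.null(tab[[id]])) stop("not found: ", id, call. = FALSE)
  tab[[id]]
}

#' Session history of a person
#'
#' @param store An [open_store()] handle.
#' @param person_id An existing person id.
#' @return List of session documents sorted by date ascending (possibly
#'   empty).
#' @export
store_history <- function(store, person_id) {
  doc <- read_store_doc(store)
  if (is.null(doc$persons[[person_id]]))
    stop("unknown person_id: ", person_id, call. = FALSE)
  ses <- Filter(function(s) identical(s$person_id, person_id), doc$sessions)
  ses <- unname(ses)
  if (length(ses))
    ses <- ses[order(vapply(ses, function(s) s$date, character(1)))]
  ses
}

#' Export stored results as a long table
#'
#' One row per stored item result, suitable as input to the
#' agreement-report tooling or for longitudinal series per item.
#'
#' @param store An [open_store()] handle.
#' @param person_id Optional filter.
#' @return Data frame `person_id`, `session_id`, `session_date`,
#'   `test_code`, `value`, `source`.
#' @export
export_results <- function(store, person_id = NULL) {
  doc <- read_store_doc(store)
  rows <- list()
  for (s in doc$sessions) {
    if (!is.null(person_id) && !identical(s$person_id, person_id)) next
    for (r in s$item_results)
      rows[[length(rows) + 1L]] <- data.frame(
        person_id = s$person_id, session_id = s$session_id,
        session_date = s$date, test_code = r$test_code,
        value = as.numeric(r$value), source = r$source,
        stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(person_id = character(), session_id = character(),
                      session_date = character(), test_code = character(),
                      value = numeric(), source = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out[order(out$person_id, out$session_date), , drop = FALSE]
}
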