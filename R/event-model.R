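# Event-log schema: vocabularies, record validation, JSON-lines IO.
#
# One record is one timestamped telemetry row for an anonymous installation.
# The on-disk format is JSON-lines (UTF-8, one object per line) with
# epoch-millisecond integer timestamps:
#   {"install_id":"u000001","timestamp_ms":1533081600000,
#    "event_name":"screen_view","content_area":"training_plan",
#    "duration_s":12.5,"payload":{"level":2}}

#' Event-name vocabulary
#'
#' Fixed vocabulary for the `event_name` field.  Unknown names map to
#' `"other"` with a warning when validating, so an evolving app vocabulary
#' degrades gracefully rather than dropping records.
#' @export
EVENT_NAMES <- c(
  "launch", "eula_accepted", "screen_view", "exercise_started",
  "level_completed", "assessment_item", "assessment_completed", "other"
)

#' Content-area vocabulary
#'
#' The app's primary destinations plus `home` (the landing screen, never
#' counted as a content area in navigation analyses) and an `other`
#' catch-all.
#' @export
CONTENT_AREAS <- c(
  "training_plan", "practice_now", "build_expertise", "track_progress",
  "badges", "other", "home"
)

# content_area is required for screen_view, optional for exercise_started
# and other, and must be absent elsewhere (those events carry no screen
# context).
AREA_REQUIRED <- "screen_view"
AREA_OPTIONAL <- c("exercise_started", "other")

#' Empty event-record table
#'
#' Zero-row data.frame with the typed columns of the event schema; the
#' template every record table is coerced against.
#' @return zero-row data.frame.
#' @export
empty_records <- function() {
  data.frame(
    install_id = character(0), timestamp_ms = numeric(0),
    event_name = character(0), content_area = character(0),
    duration_s = numeric(0), level = integer(0), item = character(0),
    response = integer(0), platform = character(0), cap_s = numeric(0),
    stringsAsFactors = FALSE
  )
}

#' Validate one raw event record
#'
#' Checks a key/value map against the event schema.  Validation is
#' all-or-nothing: either a fully typed record comes back, or the complete
#' list of violations does (never a partially repaired record).  Content
#' errors never raise conditions; only programming errors do.
#'
#' @param raw named list (e.g. one parsed JSON-lines object).  Optional
#'   `payload` sub-list may carry `level`, `item`, `response`, `platform`,
#'   `cap_s`.
#' @return an object of class `event_record` (a named list) on success,
#'   otherwise a character vector of violations.
#' @examples
#' validate_record(list(install_id = "u1", timestamp_ms = 0,
#'                      event_name = "launch", duration_s = 2))
#' validate_record(list(timestamp_ms = 0, event_name = "launch",
#'                      duration_s = 2))  # "install_id missing"
#' @export
validate_record <- function(raw) {
  errs <- character(0)
  if (!is.list(raw)) return("record is not a key/value map")

  scalar_chr <- function(x) is.character(x) && length(x) == 1L && !is.na(x)
  scalar_num <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x)

  id <- raw$install_id
  if (is.null(id) || !scalar_chr(id) || !nzchar(id)) {
    errs <- c(errs, "install_id missing or empty")
  }

  ts <- raw$timestamp_ms
  if (is.null(ts) || !scalar_num(ts) || !is.finite(ts)) {
    errs <- c(errs, "timestamp_ms missing or non-numeric")
  } else if (abs(ts) > 2^52) {
    errs <- c(errs, "timestamp_ms outside representable range")
  }

  ev <- raw$event_name
  if (is.null(ev) || !scalar_chr(ev)) {
    errs <- c(errs, "event_name missing")
    ev <- NA_character_
  } else if (!ev %in% EVENT_NAMES) {
    warning(sprintf("unknown event_name '%s' mapped to 'other'", ev),
            call. = FALSE)
    ev <- "other"
  }

  dur <- raw$duration_s
  if (is.null(dur) || !scalar_num(dur)) {
    errs <- c(errs, "duration_s missing or non-numeric")
  } else if (dur < 0) {
    errs <- c(errs, "duration_s negative")
  }

  area <- raw$content_area
  if (!is.null(area)) {
    if (!scalar_chr(area)) {
      errs <- c(errs, "content_area not a string")
      area <- NA_character_
    } else if (!area %in% CONTENT_AREAS) {
      warning(sprintf("unknown content_area '%s' mapped to 'other'", area),
              call. = FALSE)
      area <- "other"
    }
  }
  if (!is.na(ev)) {
    if (ev %in% AREA_REQUIRED && is.null(area)) {
      errs <- c(errs, "content_area required for screen_view")
    }
    if (!ev %in% c(AREA_REQUIRED, AREA_OPTIONAL) && !is.null(area)) {
      errs <- c(errs, sprintf("content_area not allowed for %s", ev))
    }
  }

  pl <- raw$payload %||% list()
  if (!is.list(pl)) {
    errs <- c(errs, "payload not a key/value map")
    pl <- list()
  }
  if (identical(ev, "assessment_item")) {
    if (is.null(pl$item) || !scalar_chr(pl$item)) {
      errs <- c(errs, "payload item missing for assessment_item")
    }
    if (is.null(pl$response) || !scalar_num(pl$response)) {
      errs <- c(errs, "payload response missing for assessment_item")
    } else if (!pl$response %in% 1:5) {
      errs <- c(errs, "payload response outside 1-5")
    }
  }
  if (identical(ev, "level_completed")) {
    if (is.null(pl$level) || !scalar_num(pl$level) || !pl$level %in% 1:14) {
      errs <- c(errs, "payload level missing or outside 1-14 for level_completed")
    }
  }
  if (!is.null(pl$cap_s) && (!scalar_num(pl$cap_s) || pl$cap_s <= 0)) {
    errs <- c(errs, "payload cap_s must be a positive number")
  }

  if (length(errs)) return(errs)

  structure(list(
    install_id = id, timestamp_ms = as.numeric(ts), event_name = ev,
    content_area = if (is.null(area)) NA_character_ else area,
    duration_s = as.numeric(dur),
    level = if (is.null(pl$level)) NA_integer_ else as.integer(pl$level),
    item = if (is.null(pl$item)) NA_character_ else pl$item,
    response = if (is.null(pl$response)) NA_integer_ else as.integer(pl$response),
    platform = if (is.null(pl$platform)) NA_character_ else pl$platform,
    cap_s = if (is.null(pl$cap_s)) NA_real_ else as.numeric(pl$cap_s)
  ), class = "event_record")
}

record_to_row <- function(rec) {
  as.data.frame(unclass(rec), stringsAsFactors = FALSE)
}

#' Construct an event stream
#'
#' Wraps a typed record table as a validated, sorted `event_stream`.  Records
#' are stably sorted by installation then timestamp (ties keep input order).
#' The observation window defaults to the span of the data; an explicit
#' window must contain every timestamp, because all retention arithmetic
#' censors at `window_end`.
#'
#' @param records data.frame with the columns of [empty_records()].
#' @param source provenance string.
#' @param window_start,window_end observation-period bounds: POSIXct,
#'   date-time strings (UTC) or epoch milliseconds.
#' @param n_skipped count of malformed input lines dropped upstream.
#' @return an object of class `event_stream`: list with elements `records`,
#'   `source`, `window_start_ms`, `window_end_ms`, `n_skipped`.
#' @export
event_stream <- function(records, source = "memory",
                         window_start = NULL, window_end = NULL,
                         n_skipped = 0L) {
  tmpl <- empty_records()
  missing_cols <- setdiff(names(tmpl), names(records))
  for (cl in missing_cols) records[[cl]] <- rep(tmpl[[cl]][NA], nrow(records))
  records <- records[names(tmpl)]
  if (nrow(records)) {
    if (any(!nzchar(records$install_id)) || anyNA(records$install_id)) {
      stop("install_id must be nonempty for every record")
    }
    if (any(records$duration_s < 0)) stop("duration_s must be nonnegative")
    records <- records[stream_order(records$install_id, records$timestamp_ms), ,
                       drop = FALSE]
    rownames(records) <- NULL
  }
  ws <- if (is.null(window_start)) {
    if (nrow(records)) min(records$timestamp_ms) else 0
  } else posix_to_ms(window_start)
  we <- if (is.null(window_end)) {
    if (nrow(records)) max(records$timestamp_ms) else 0
  } else posix_to_ms(window_end)
  if (ws > we) stop("window_start must not exceed window_end")
  if (nrow(records) &&
      (min(records$timestamp_ms) < ws || max(records$timestamp_ms) > we)) {
    stop("observation window must contain every event timestamp")
  }
  structure(list(records = records, source = source,
                 window_start_ms = ws, window_end_ms = we,
                 n_skipped = as.integer(n_skipped)),
            class = "event_stream")
}

#' @method print event_stream
#' @export
print.event_stream <- function(x, ...) {
  cat(sprintf(
    "<event_stream> %d records, %d installations\n  window: %s .. %s (UTC)\n  source: %s%s\n",
    nrow(x$records), length(unique(x$records$install_id)),
    format(ms_to_posix(x$window_start_ms)), format(ms_to_posix(x$window_end_ms)),
    x$source,
    if (x$n_skipped > 0) sprintf("  [%d malformed lines skipped]", x$n_skipped) else ""
  ))
  invisible(x)
}

#' @export
as.data.frame.event_stream <- function(x, ...) x$records

#' Read a JSON-lines event log
#'
#' Parses and validates one JSON object per line.  In strict mode the first
#' malformed line aborts with its line number; otherwise malformed lines are
#' skipped, counted, and reported via a message.  `.gz` compressed logs are
#' read transparently.
#'
#' @param path file path (plain or gzip JSON-lines).
#' @param strict abort on first malformed line instead of skipping.
#' @param window_start,window_end optional observation-window bounds passed
#'   to [event_stream()].
#' @return an `event_stream`.
#' @export
read_event_log <- function(path, strict = FALSE,
                           window_start = NULL, window_end = NULL) {
  if (!file.exists(path)) stop(sprintf("event log not found: %s", path))
  con <- gzfile(path, open = "rt", encoding = "UTF-8")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  keep <- nzchar(trimws(lines))
  idx <- which(keep)
  rows <- vector("list", length(idx))
  n_bad <- 0L
  for (k in seq_along(idx)) {
    i <- idx[k]
    parsed <- tryCatch(
      jsonlite::fromJSON(lines[[i]], simplifyVector = TRUE,
                         simplifyDataFrame = FALSE),
      error = function(e) e
    )
    bad <- NULL
    if (inherits(parsed, "error")) {
      bad <- sprintf("line %d: invalid JSON (%s)", i, conditionMessage(parsed))
    } else {
      rec <- validate_record(parsed)
      if (!inherits(rec, "event_record")) {
        bad <- sprintf("line %d: %s", i, paste(rec, collapse = "; "))
      } else {
        rows[[k]] <- record_to_row(rec)
      }
    }
    if (!is.null(bad)) {
      if (strict) stop(bad, call. = FALSE)
      n_bad <- n_bad + 1L
    }
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  records <- if (length(rows)) do.call(rbind, rows) else empty_records()
  if (n_bad > 0L) {
    message(sprintf("read_event_log: skipped %d malformed line(s) in %s",
                    n_bad, path))
  }
  event_stream(records, source = path, window_start = window_start,
               window_end = window_end, n_skipped = n_bad)
}

json_escape <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub('"', '\\"', x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  gsub("\t", "\\t", x, fixed = TRUE)
}

# Serialize numbers so the round-trip is lossless: integers print without
# exponent, fractional durations keep full precision.
json_num <- function(x) {
  ifelse(x == round(x), sprintf("%.0f", x),
         vapply(x, function(v) format(v, digits = 15, scientific = FALSE),
                character(1)))
}

#' Write a JSON-lines event log
#'
#' Inverse of [read_event_log()]: `read_event_log(write_event_log(s))`
#' reproduces `s` record for record.  Paths ending in `.gz` are written
#' gzip-compressed.
#'
#' @param stream a validated `event_stream`.
#' @param path output file path.
#' @return number of records written, invisibly.
#' @export
write_event_log <- function(stream, path) {
  stopifnot(inherits(stream, "event_stream"))
  r <- stream$records
  n <- nrow(r)
  if (n == 0L) {
    con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
    close(con)
    return(invisible(0L))
  }
  payload_parts <- function(key, val, quote) {
    out <- character(n)
    has <- !is.na(val)
    out[has] <- if (quote) {
      sprintf('"%s":"%s"', key, json_escape(val[has]))
    } else sprintf('"%s":%s', key, json_num(as.numeric(val[has])))
    out
  }
  pp <- cbind(
    payload_parts("level", r$level, FALSE),
    payload_parts("item", r$item, TRUE),
    payload_parts("response", r$response, FALSE),
    payload_parts("platform", r$platform, TRUE),
    payload_parts("cap_s", r$cap_s, FALSE)
  )
  payload <- apply(pp, 1L, function(p) paste(p[nzchar(p)], collapse = ","))
  area <- ifelse(is.na(r$content_area), "",
                 sprintf(',"content_area":"%s"', r$content_area))
  lines <- sprintf(
    '{"install_id":"%s","timestamp_ms":%s,"event_name":"%s"%s,"duration_s":%s%s}',
    json_escape(r$install_id), json_num(r$timestamp_ms), r$event_name, area,
    json_num(r$duration_s),
    ifelse(nzchar(payload), sprintf(',"payload":{%s}', payload), "")
  )
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(n)
}
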