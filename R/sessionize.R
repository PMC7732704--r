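# Sessionization: durations are capped, events are clustered into visits by
# an inactivity gap, and each visit is typed first-time or return.
#
# Definitions implemented here:
#  * an *event* is a record with nonzero duration (zero-duration records are
#    clicks in time: they anchor visit boundaries but are not counted);
#  * a *visit* is a maximal cluster of records less than `gap_s` apart
#    (start-to-start gaps; a gap of exactly `gap_s` splits);
#  * a visit is *first-time* iff it contains the EULA-acceptance event,
#    otherwise it is a *return* visit.

#' Cap an event duration
#'
#' Durations are truncated at the cap (default 30 minutes = 1800 s) unless
#' the user specified a longer value, in which case the user's value becomes
#' the effective cap.
#'
#' @param duration_s nonnegative duration in seconds (vectorized).
#' @param cap_s default cap in seconds.
#' @param user_override_s optional user-specified cap; only raises the cap,
#'   never lowers it.
#' @return capped duration in seconds.
#' @examples
#' cap_duration(100)          # 100
#' cap_duration(5000)         # 1800
#' cap_duration(5000, user_override_s = 7200)  # 5000
#' @export
cap_duration <- function(duration_s, cap_s = 1800, user_override_s = NULL) {
  if (any(duration_s < 0)) stop("duration_s must be nonnegative")
  if (cap_s <= 0) stop("cap_s must be positive")
  eff <- cap_s
  if (!is.null(user_override_s) && !all(is.na(user_override_s))) {
    if (any(user_override_s <= 0, na.rm = TRUE)) {
      stop("user_override_s must be positive")
    }
    ov <- ifelse(is.na(user_override_s), cap_s, user_override_s)
    eff <- pmax(cap_s, ov)
  }
  pmin(duration_s, eff)
}

#' Is a record a countable event?
#'
#' A record counts as an in-app interaction ("event") iff its duration field
#' is nonzero.
#'
#' @param record an `event_record`, or a data.frame of records.
#' @return logical.
#' @export
is_countable_event <- function(record) {
  if (is.data.frame(record)) return(record$duration_s > 0)
  record$duration_s > 0
}

# Visit-id assignment over a sorted record table (possibly many installs):
# a new visit starts at each install change or whenever the start-to-start
# gap reaches gap_s * 1000 ms.  Returns integer visit ids, global across the
# table, increasing in table order.
assign_visit_ids <- function(install_id, timestamp_ms, gap_s = 1800) {
  n <- length(install_id)
  if (n == 0L) return(integer(0))
  gap_ms <- gap_s * 1000
  new_install <- c(TRUE, install_id[-1L] != install_id[-n])
  gap <- c(Inf, timestamp_ms[-1L] - timestamp_ms[-n])
  if (any(gap < 0 & !new_install)) stop("records must be sorted by timestamp within install")
  cumsum(new_install | gap >= gap_ms)
}

#' Cluster one installation's records into visits
#'
#' Partitions a sorted single-installation record table into visits: a new
#' visit starts whenever the gap to the previous record is `gap_s` seconds
#' or more (records strictly less than `gap_s` apart stay together).
#'
#' @param events data.frame of records for one installation, sorted by
#'   timestamp.
#' @param gap_s inactivity gap in seconds (default 1800 = 30 minutes).
#' @return list of data.frames, one per visit, in chronological order.
#' @export
cluster_visits <- function(events, gap_s = 1800) {
  stopifnot(is.data.frame(events))
  if (nrow(events) == 0L) return(list())
  if (length(unique(events$install_id)) != 1L) {
    stop("cluster_visits expects records from a single installation")
  }
  if (is.unsorted(events$timestamp_ms)) stop("records must be sorted by timestamp")
  vid <- assign_visit_ids(events$install_id, events$timestamp_ms, gap_s)
  unname(split(events, vid))
}

#' Classify a visit as first-time or return
#'
#' A visit is the installation's first-time use iff the end-user license
#' agreement was accepted during it; every other visit is a return visit.
#' Installations with no EULA event anywhere (downloaded, never accepted)
#' have all visits typed `"return"` and are flagged via
#' `accepted_license = FALSE` on their timeline.
#'
#' @param visit data.frame of one visit's records.
#' @return `"first_time"` or `"return"`.
#' @export
classify_session <- function(visit) {
  if (any(visit$event_name == "eula_accepted")) "first_time" else "return"
}

# Effective per-install duration cap: the largest user-specified cap seen in
# any settings payload, if one exists.
install_cap_override <- function(events) {
  if (all(is.na(events$cap_s))) return(NA_real_)
  max(events$cap_s, na.rm = TRUE)
}

#' Sessionize a whole event stream
#'
#' Vectorized core of the sessionizer: assigns every record to a visit,
#' caps durations, marks countable events, and summarizes visits.  All
#' higher-level analyses (profiles, retention, navigation) run off this
#' output.
#'
#' @param stream an `event_stream`.
#' @param gap_s inactivity gap defining visit boundaries (seconds).
#' @param cap_s duration cap (seconds); per-install user overrides from
#'   settings payloads can raise it.
#' @return list of class `sessionized` with elements
#'   \describe{
#'     \item{events}{record table plus `visit_id`, `visit_index`,
#'       `capped_s`, `countable`.}
#'     \item{visits}{one row per visit: `install_id`, `visit_index`,
#'       `start_ms`, `end_ms`, `n_records`, `n_events`, `active_seconds`,
#'       `session_type`.}
#'     \item{gap_s, cap_s}{parameters used.}
#'   }
#' @export
sessionize_stream <- function(stream, gap_s = 1800, cap_s = 1800) {
  stopifnot(inherits(stream, "event_stream"))
  ev <- stream$records
  n <- nrow(ev)
  if (n == 0L) {
    visits <- data.frame(install_id = character(0), visit_index = integer(0),
                         start_ms = numeric(0), end_ms = numeric(0),
                         n_records = integer(0), n_events = integer(0),
                         active_seconds = numeric(0),
                         session_type = character(0),
                         stringsAsFactors = FALSE)
    ev$visit_id <- integer(0); ev$visit_index <- integer(0)
    ev$capped_s <- numeric(0); ev$countable <- logical(0)
    return(structure(list(events = ev, visits = visits,
                          gap_s = gap_s, cap_s = cap_s),
                     class = "sessionized"))
  }

  # per-install cap override (max cap_s payload seen for that install)
  has_cap <- !is.na(ev$cap_s)
  override <- rep(NA_real_, n)
  if (any(has_cap)) {
    ov_by_install <- tapply(ev$cap_s[has_cap], ev$install_id[has_cap], max)
    override <- as.numeric(ov_by_install[ev$install_id])
  }
  eff_cap <- pmax(cap_s, ifelse(is.na(override), cap_s, override))
  ev$capped_s <- pmin(ev$duration_s, eff_cap)
  ev$countable <- ev$duration_s > 0

  ev$visit_id <- assign_visit_ids(ev$install_id, ev$timestamp_ms, gap_s)
  first_of_visit <- !duplicated(ev$visit_id)
  ev$visit_index <- group_cumsum(as.numeric(first_of_visit), ev$install_id)

  vid <- ev$visit_id
  visits <- data.frame(
    install_id = ev$install_id[first_of_visit],
    visit_index = as.integer(ev$visit_index[first_of_visit]),
    start_ms = ev$timestamp_ms[first_of_visit],
    end_ms = as.numeric(tapply(ev$timestamp_ms, vid, max)),
    n_records = as.integer(tabulate(vid)),
    n_events = as.integer(rowsum(as.numeric(ev$countable), vid)[, 1L]),
    active_seconds = as.numeric(rowsum(ev$capped_s * ev$countable, vid)[, 1L]),
    stringsAsFactors = FALSE
  )
  has_eula <- rowsum(as.numeric(ev$event_name == "eula_accepted"), vid)[, 1L] > 0
  visits$session_type <- ifelse(has_eula, "first_time", "return")

  eulas_per_install <- tapply(ev$event_name == "eula_accepted", ev$install_id, sum)
  if (any(eulas_per_install > 1L)) {
    bad <- names(eulas_per_install)[eulas_per_install > 1L]
    stop(sprintf("multiple EULA events for installation(s): %s",
                 paste(utils::head(bad, 5L), collapse = ", ")))
  }

  structure(list(events = ev, visits = visits, gap_s = gap_s, cap_s = cap_s),
            class = "sessionized")
}

#' @method print sessionized
#' @export
print.sessionized <- function(x, ...) {
  cat(sprintf("<sessionized> %d visits over %d installations (gap %ds, cap %ds)\n",
              nrow(x$visits), length(unique(x$visits$install_id)),
              x$gap_s, x$cap_s))
  invisible(x)
}

#' Assemble one installation's timeline
#'
#' Caps, clusters and classifies a single installation's records into an
#' ordered visit timeline.
#'
#' @param stream an `event_stream` containing the installation.
#' @param install_id installation identifier.
#' @param gap_s,cap_s sessionization parameters (seconds).
#' @return object of class `user_timeline`: list with `install_id`,
#'   `visits` (list of per-visit record data.frames, each with `capped_s`,
#'   `countable` and a `session_type` attribute), `first_use_ms`,
#'   `last_use_ms`, `accepted_license`.
#' @export
build_timeline <- function(stream, install_id, gap_s = 1800, cap_s = 1800) {
  stopifnot(inherits(stream, "event_stream"))
  ev <- stream$records[stream$records$install_id == install_id, , drop = FALSE]
  if (nrow(ev) == 0L) stop(sprintf("unknown install_id: %s", install_id))
  if (sum(ev$event_name == "eula_accepted") > 1L) {
    stop(sprintf("multiple EULA events for installation %s", install_id))
  }
  ov <- install_cap_override(ev)
  ev$capped_s <- cap_duration(ev$duration_s, cap_s,
                              if (is.na(ov)) NULL else ov)
  ev$countable <- is_countable_event(ev)
  visits <- cluster_visits(ev, gap_s)
  visits <- lapply(visits, function(v) {
    attr(v, "session_type") <- classify_session(v)
    v
  })
  structure(list(
    install_id = install_id,
    visits = visits,
    first_use_ms = visits[[1L]]$timestamp_ms[1L],
    last_use_ms = max(ev$timestamp_ms),
    accepted_license = any(ev$event_name == "eula_accepted")
  ), class = "user_timeline")
}

#' @method print user_timeline
#' @export
print.user_timeline <- function(x, ...) {
  cat(sprintf("<user_timeline> %s: %d visits, %s .. %s, license %s\n",
              x$install_id, length(x$visits),
              format(ms_to_posix(x$first_use_ms)),
              format(ms_to_posix(x$last_use_ms)),
              if (x$accepted_license) "accepted" else "not accepted"))
  invisible(x)
}
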