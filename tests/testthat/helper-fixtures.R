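# Fixture builders used across the suite.  All fixtures are constructed in
# code; timestamps count from a fixed UTC origin.

T0 <- as.numeric(as.POSIXct("2018-08-01", tz = "UTC")) * 1000

# Build a record table from vectors; `at_s` are offsets in seconds from T0.
fix_events <- function(install_id, at_s, event_name = "other",
                       duration_s = 10, content_area = NA_character_,
                       level = NA_integer_, item = NA_character_,
                       response = NA_integer_, platform = NA_character_,
                       cap_s = NA_real_) {
  n <- length(at_s)
  data.frame(
    install_id = rep_len(install_id, n),
    timestamp_ms = T0 + at_s * 1000,
    event_name = rep_len(event_name, n),
    content_area = rep_len(content_area, n),
    duration_s = rep_len(duration_s, n),
    level = rep_len(as.integer(level), n),
    item = rep_len(item, n),
    response = rep_len(as.integer(response), n),
    platform = rep_len(platform, n),
    cap_s = rep_len(cap_s, n),
    stringsAsFactors = FALSE
  )
}

fix_stream <- function(..., window_start = NULL, window_end = NULL) {
  event_stream(do.call(rbind, list(...)), source = "fixture",
               window_start = window_start, window_end = window_end)
}

# A two-visit, one-user timeline: visit 1 (launch+eula+screens) at t=0,
# visit 2 at t=2h.
fix_two_visit_user <- function(id = "u1") {
  rbind(
    fix_events(id, 0, "launch", 5, platform = "android"),
    fix_events(id, 10, "eula_accepted", 20),
    fix_events(id, 40, "screen_view", 30, content_area = "home"),
    fix_events(id, 80, "screen_view", 60, content_area = "training_plan"),
    fix_events(id, 7200, "launch", 5),
    fix_events(id, 7230, "screen_view", 45, content_area = "practice_now")
  )
}

# Brute-force O(n^2) visit partitioner: union all pairs of records less
# than gap_s apart, then read off connected components in time order.
brute_force_visits <- function(timestamps_ms, gap_s = 1800) {
  n <- length(timestamps_ms)
  if (n == 0L) return(integer(0))
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && abs(timestamps_ms[i] - timestamps_ms[j]) < gap_s * 1000) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  as.integer(factor(roots, levels = unique(roots)))
}

# Minimal valid raw record for validate_record()
raw_record <- function(...) {
  utils::modifyList(list(install_id = "u1", timestamp_ms = T0,
                         event_name = "launch", duration_s = 2), list(...))
}

ffmq_all <- function(value, key = ffmq_key()) {
  stats::setNames(rep(value, length(key$items)), key$items)
}

# A key with no reverse-scored items (same 19-item structure)
key_no_reverse <- function() {
  k <- ffmq_key()
  k$reverse <- character(0)
  k
}
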