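# Occasion extraction.  The common case -- a visit holding exactly the 19
# distinct key items plus a completion event -- is scored fully vectorized;
# visits with duplicates, missing items, or foreign item ids fall back to a
# per-occasion path through score_occasion().

empty_scores <- function() {
  data.frame(
    install_id = character(0), occasion = integer(0), timestamp_ms = numeric(0),
    weeks_since_install = numeric(0), level_at_assessment = integer(0),
    observing = numeric(0), acting_with_awareness = numeric(0),
    nonjudging = numeric(0), nonreactivity = numeric(0), total = numeric(0),
    stringsAsFactors = FALSE
  )
}

# Highest completed level at or before each occasion timestamp; defaults
# to 1.  `lev` holds level_completed events (sorted by install, time).
level_at_times <- function(occ_install, occ_ts, lev) {
  out <- rep(1L, length(occ_install))
  if (!nrow(lev) || !length(occ_install)) return(out)
  lv_split <- split(lev[c("timestamp_ms", "level")], lev$install_id)
  oc_split <- split(seq_along(occ_install), occ_install)
  for (id in intersect(names(oc_split), names(lv_split))) {
    lv <- lv_split[[id]]
    cm <- cummax(lv$level)
    idx <- findInterval(occ_ts[oc_split[[id]]], lv$timestamp_ms)
    out[oc_split[[id]]] <- ifelse(idx > 0, cm[pmax(idx, 1L)], 1L)
  }
  out
}

#' Extract and score assessment occasions
#'
#' Finds FFMQ-SF occasions in a sessionized stream: within each visit,
#' `assessment_item` events closed by an `assessment_completed` event form
#' one occasion; item runs never closed are counted as abandonments and not
#' scored.  Duplicate item ids within an occasion keep the last response
#' (with a warning).  Occasions missing items are dropped (counted) under
#' the default missing policy.
#'
#' @param sess a `sessionized` object.
#' @param key an `ffmq_key`.
#' @param missing missing-item policy, see [score_occasion()].
#' @return data.frame of class `ffmq_scores`: `install_id`, `occasion`,
#'   `timestamp_ms`, `weeks_since_install`, `level_at_assessment`, the four
#'   subscale scores, `total`.  Attributes `n_abandoned` and `n_incomplete`
#'   count unscored runs.
#' @export
extract_assessments <- function(sess, key = ffmq_key(),
                                missing = c("reject", "prorate")) {
  missing <- match.arg(missing)
  stopifnot(inherits(sess, "sessionized"))
  ev <- sess$events
  it <- ev[ev$event_name == "assessment_item", , drop = FALSE]
  dn <- ev[ev$event_name == "assessment_completed", , drop = FALSE]
  n_abandoned <- 0L
  n_incomplete <- 0L
  if (!nrow(it) || !nrow(dn)) {
    n_abandoned <- length(unique(it$visit_id))
    out <- empty_scores()
    attr(out, "n_abandoned") <- n_abandoned
    attr(out, "n_incomplete") <- 0L
    class(out) <- c("ffmq_scores", class(out))
    return(out)
  }

  # occasion timestamp: last completion event in the visit
  done_ts <- tapply(dn$timestamp_ms, dn$visit_id, max)
  done_vids <- as.numeric(names(done_ts))
  item_vids <- unique(it$visit_id)
  n_abandoned <- sum(!item_vids %in% done_vids)
  cand <- intersect(item_vids, done_vids)
  it <- it[it$visit_id %in% cand, , drop = FALSE]

  # classify candidate visits: fast path needs the exact 19 distinct key
  # items with integer responses
  vf <- factor(it$visit_id, levels = cand)
  n_items <- as.integer(table(vf))
  has_dup <- tapply(it$item, vf, anyDuplicated) > 0L
  all_key <- tapply(it$item %in% key$items & !is.na(it$response), vf, all)
  fast <- n_items == 19L & !has_dup & all_key
  fast_vids <- cand[fast]

  rows <- list()
  if (length(fast_vids)) {
    fi <- it[it$visit_id %in% fast_vids, , drop = FALSE]
    scored <- ifelse(fi$item %in% key$reverse,
                     (key$scale_min + key$scale_max) - fi$response,
                     as.numeric(fi$response))
    sub_of_item <- stats::setNames(
      rep(names(key$subscales), lengths(key$subscales)),
      unlist(key$subscales, use.names = FALSE))
    sub <- sub_of_item[fi$item]
    gf <- factor(fi$visit_id, levels = fast_vids)
    agg <- function(s) as.numeric(rowsum(scored * (sub == s), gf))
    rows[["fast"]] <- data.frame(
      visit_id = fast_vids,
      observing = agg("observing"),
      acting_with_awareness = agg("acting_with_awareness"),
      nonjudging = agg("nonjudging"),
      nonreactivity = agg("nonreactivity"),
      stringsAsFactors = FALSE
    )
    rows[["fast"]]$total <- rows[["fast"]]$observing +
      rows[["fast"]]$acting_with_awareness + rows[["fast"]]$nonjudging +
      rows[["fast"]]$nonreactivity
  }

  slow_vids <- cand[!fast]
  if (length(slow_vids)) {
    dup_warned <- FALSE
    si <- it[it$visit_id %in% slow_vids, , drop = FALSE]
    slow_rows <- vector("list", length(slow_vids))
    by_vid <- split(si, factor(si$visit_id, levels = slow_vids))
    for (k in seq_along(slow_vids)) {
      items <- by_vid[[k]]
      if (anyDuplicated(items$item)) {
        if (!dup_warned) {
          warning("duplicate item id(s) within an occasion; keeping the last response",
                  call. = FALSE)
          dup_warned <- TRUE
        }
        items <- items[!duplicated(items$item, fromLast = TRUE), , drop = FALSE]
      }
      responses <- stats::setNames(as.numeric(items$response), items$item)
      sc <- tryCatch(score_occasion(responses, key, missing = missing),
                     error = function(e) e)
      if (inherits(sc, "error")) {
        n_incomplete <- n_incomplete + 1L
        next
      }
      slow_rows[[k]] <- data.frame(
        visit_id = slow_vids[k], observing = sc$observing,
        acting_with_awareness = sc$acting_with_awareness,
        nonjudging = sc$nonjudging, nonreactivity = sc$nonreactivity,
        total = sc$total, stringsAsFactors = FALSE
      )
    }
    slow_rows <- slow_rows[!vapply(slow_rows, is.null, logical(1))]
    if (length(slow_rows)) rows[["slow"]] <- do.call(rbind, slow_rows)
  }

  if (!length(rows)) {
    out <- empty_scores()
  } else {
    sc <- do.call(rbind, rows)
    vmeta <- sess$visits[match(sc$visit_id,
                               sess$events$visit_id[!duplicated(sess$events$visit_id)]), ]
    sc$install_id <- vmeta$install_id
    sc$timestamp_ms <- as.numeric(done_ts[as.character(sc$visit_id)])
    first_use <- tapply(ev$timestamp_ms, ev$install_id, min)
    sc$weeks_since_install <-
      (sc$timestamp_ms - as.numeric(first_use[sc$install_id])) / MS_WEEK
    lev <- ev[ev$event_name == "level_completed" & !is.na(ev$level), , drop = FALSE]
    sc$level_at_assessment <- level_at_times(sc$install_id, sc$timestamp_ms, lev)
    sc <- sc[order(sc$install_id, sc$timestamp_ms, method = "radix"), , drop = FALSE]
    sc$occasion <- as.integer(stats::ave(seq_len(nrow(sc)), sc$install_id,
                                         FUN = seq_along))
    out <- sc[c("install_id", "occasion", "timestamp_ms", "weeks_since_install",
                "level_at_assessment", "observing", "acting_with_awareness",
                "nonjudging", "nonreactivity", "total")]
    rownames(out) <- NULL
  }
  attr(out, "n_abandoned") <- n_abandoned
  attr(out, "n_incomplete") <- n_incomplete
  class(out) <- c("ffmq_scores", class(out))
  out
}
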