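# Click-stream navigation analysis: which content areas sessions touch,
# split by first-time vs returning sessions, with a between-group
# chi-square comparison.
#
# The home screen is never a content area: a session that only ever shows
# `home` contributes to the "0 content areas" row.

AREA_LABELS <- setdiff(CONTENT_AREAS, "home")

#' First content area of a visit
#'
#' The content area of the first `screen_view` event in the visit whose
#' area is not `home`; `NA` when the visit never leaves the home screen
#' (or shows no screens at all).  Order-dependent by construction:
#' permuting later events never changes it.
#'
#' @param visit data.frame of one visit's records, in time order.
#' @return area label or `NA_character_`.
#' @export
first_content_area <- function(visit) {
  if (!nrow(visit)) return(NA_character_)
  sv <- visit$event_name == "screen_view" & !is.na(visit$content_area) &
    visit$content_area != "home"
  if (!any(sv)) return(NA_character_)
  visit$content_area[which(sv)[1L]]
}

# Per-visit navigation facts, vectorized over a sessionized stream:
# first non-home area, number of area entries, distinct areas.
visit_navigation <- function(sess) {
  ev <- sess$events
  vs <- sess$visits
  sv <- ev[ev$event_name == "screen_view" & !is.na(ev$content_area) &
             ev$content_area != "home", , drop = FALSE]
  vs$first_area <- NA_character_
  vs$n_distinct <- 0L
  entries <- NULL
  if (nrow(sv)) {
    first_in_visit <- !duplicated(sv$visit_id)
    vs$first_area[match(sv$visit_id[first_in_visit], ev$visit_id[!duplicated(ev$visit_id)])] <-
      sv$content_area[first_in_visit]
    # an "entry" is a maximal run of identical consecutive areas in a visit
    run_break <- c(TRUE, sv$visit_id[-1L] != sv$visit_id[-nrow(sv)] |
                     sv$content_area[-1L] != sv$content_area[-nrow(sv)])
    entries <- sv[run_break, c("visit_id", "content_area"), drop = FALSE]
    nd <- tapply(sv$content_area, sv$visit_id,
                 function(a) length(unique(a)))
    vids <- ev$visit_id[!duplicated(ev$visit_id)]
    hit <- match(as.numeric(names(nd)), vids)
    vs$n_distinct[hit] <- as.integer(nd)
  }
  list(visits = vs, entries = entries, visit_ids = ev$visit_id[!duplicated(ev$visit_id)])
}

#' Session-level navigation tables
#'
#' Builds the three navigation panels, each split by session type
#' (first-time vs return):
#' \describe{
#'   \item{first_area}{first content area visited; denominator = sessions
#'     that visited at least one content area.}
#'   \item{any_area}{content-area entries (a session entering an area,
#'     leaving, and entering another contributes several entries);
#'     denominator = all entries.}
#'   \item{n_distinct_areas}{number of distinct content areas per session;
#'     denominator = all sessions, home-only sessions count 0.}
#' }
#' Each panel gets a Pearson chi-square comparison between session types.
#'
#' @param sess a `sessionized` object.
#' @return list of class `navigation_table`: `panels` (long data.frame:
#'   panel, session_type, label, count, denominator, pct) and `tests`
#'   (panel, statistic, df, p_value).
#' @export
navigation_summary <- function(sess) {
  stopifnot(inherits(sess, "sessionized"))
  nav <- visit_navigation(sess)
  vs <- nav$visits
  types <- c("first_time", "return")
  if (!all(types %in% vs$session_type)) {
    stop("both first-time and return sessions are required")
  }
  vtype <- vs$session_type

  rows <- list()
  add <- function(panel, session_type, label, count) {
    denom <- sum(count)
    data.frame(panel = panel, session_type = session_type, label = label,
               count = as.integer(count), denominator = as.integer(denom),
               pct = if (denom > 0) proportion_pct(count, denom) else NA_real_,
               stringsAsFactors = FALSE)
  }
  for (st in types) {
    sel <- vtype == st
    fa <- vs$first_area[sel]
    fa <- fa[!is.na(fa)]
    rows[[paste0("fa_", st)]] <-
      add("first_area", st, AREA_LABELS,
          as.integer(table(factor(fa, levels = AREA_LABELS))))
    ent <- nav$entries
    ecount <- if (is.null(ent)) rep(0L, length(AREA_LABELS)) else {
      est <- vtype[match(ent$visit_id, nav$visit_ids)]
      as.integer(table(factor(ent$content_area[est == st], levels = AREA_LABELS)))
    }
    rows[[paste0("any_", st)]] <- add("any_area", st, AREA_LABELS, ecount)
  }
  maxd <- max(vs$n_distinct)
  dlev <- 0:max(maxd, 1L)
  for (st in types) {
    cnt <- as.integer(table(factor(vs$n_distinct[vtype == st], levels = dlev)))
    rows[[paste0("nd_", st)]] <-
      add("n_distinct_areas", st, as.character(dlev), cnt)
  }
  panels <- do.call(rbind, rows)
  rownames(panels) <- NULL

  tests <- do.call(rbind, lapply(unique(panels$panel), function(pn) {
    p <- panels[panels$panel == pn, ]
    m <- stats::xtabs(count ~ session_type + label, data = p)
    ct <- compare_session_types(m["first_time", ], m["return", ])
    data.frame(panel = pn, statistic = ct$statistic, df = ct$df,
               p_value = ct$p_value, stringsAsFactors = FALSE)
  }))
  rownames(tests) <- NULL
  structure(list(panels = panels, tests = tests), class = "navigation_table")
}

#' @method print navigation_table
#' @export
print.navigation_table <- function(x, ...) {
  for (pn in unique(x$panels$panel)) {
    cat(sprintf("Panel: %s\n", pn))
    print(x$panels[x$panels$panel == pn, c("session_type", "label", "count",
                                           "denominator", "pct")],
          row.names = FALSE)
    tt <- x$tests[x$tests$panel == pn, ]
    cat(sprintf("  chi-square %.2f on %d df, p %s\n\n", tt$statistic, tt$df,
                format.pval(tt$p_value, digits = 3, eps = 0.001)))
  }
  invisible(x)
}

#' Pearson chi-square comparison of two count vectors
#'
#' Compares first-time vs return label distributions with Pearson's
#' chi-square on the 2 x k contingency table (no continuity correction);
#' degrees of freedom k - 1.
#'
#' @param counts_first,counts_return counts over identical labels.
#' @param zero_expected `"collapse"` drops labels with zero total (with a
#'   warning); `"error"` aborts on any zero-expected cell.
#' @return list with `statistic`, `df`, `p_value`.
#' @examples
#' compare_session_types(c(10, 0), c(0, 10))  # statistic 20
#' @export
compare_session_types <- function(counts_first, counts_return,
                                  zero_expected = c("collapse", "error")) {
  zero_expected <- match.arg(zero_expected)
  if (length(counts_first) != length(counts_return)) {
    stop("count vectors must cover identical labels")
  }
  tot <- counts_first + counts_return
  if (all(tot == 0)) {
    warning("no positive counts; comparison undefined", call. = FALSE)
    return(list(statistic = NA_real_, df = NA_integer_, p_value = NA_real_))
  }
  if (any(tot == 0)) {
    if (zero_expected == "error") stop("zero-expected cell in comparison table")
    warning("dropping label(s) with zero total count", call. = FALSE)
    counts_first <- counts_first[tot > 0]
    counts_return <- counts_return[tot > 0]
  }
  m <- rbind(first_time = counts_first, return = counts_return)
  ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value))
}
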