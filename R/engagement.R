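# Per-installation engagement profiles, the four-category user taxonomy,
# descriptive and percentile tables, return-use and rolling retention.

CATEGORY_LEVELS <- c("exploratory", "limited", "moderate", "committed")

# Default return-use windows, in days.  Months are fixed-length here
# (30/91/182/365 days); calendar months are not used for window arithmetic.
DEFAULT_RETURN_WINDOWS <- c(
  "first day" = 1, "1 week" = 7, "1 month" = 30,
  "3 months" = 91, "6 months" = 182, "12 months" = 365
)

#' Engagement category from visit count
#'
#' Bands installations by how often they opened the app: exploratory
#' (1 visit), limited (2-3), moderate (4-7), committed (8 or more).  The
#' bands partition the positive integers.
#'
#' @param n_visits vector of visit counts (each >= 1).
#' @return factor with levels exploratory/limited/moderate/committed.
#' @examples
#' categorize(c(1, 3, 7, 8, 506))
#' @export
categorize <- function(n_visits) {
  if (any(n_visits < 1)) stop("n_visits must be >= 1")
  cut(n_visits, breaks = c(0, 1, 3, 7, Inf), labels = CATEGORY_LEVELS)
}

#' Two-stage (within-subject first) grand mean
#'
#' Computes each subject's mean first, then averages those means, so every
#' subject contributes equally to the grand mean regardless of how many
#' values it has.
#'
#' @param values either a list of per-user numeric vectors, or a data.frame
#'   with columns `install_id` and `value`.
#' @return the grand mean.
#' @examples
#' two_stage_mean(list(A = c(2, 4), B = 6))  # 4.5, not the pooled 4
#' @export
two_stage_mean <- function(values) {
  if (is.data.frame(values)) {
    values <- split(values$value, values$install_id)
  }
  if (!length(values)) stop("two_stage_mean needs at least one user")
  if (any(!vapply(values, length, integer(1)))) {
    stop("every user must contribute at least one value")
  }
  mean(vapply(values, mean, numeric(1)))
}

#' Engagement profile for one installation
#'
#' Aggregates a timeline into the per-user engagement measures: visit and
#' event counts, active minutes (sum of capped countable durations),
#' whole-week retention, highest level achieved, and engagement category.
#'
#' @param timeline a `user_timeline` from [build_timeline()].
#' @return one-row data.frame.
#' @export
profile_user <- function(timeline) {
  stopifnot(inherits(timeline, "user_timeline"))
  ev <- do.call(rbind, timeline$visits)
  lv <- ev$level[ev$event_name == "level_completed"]
  n_visits <- length(timeline$visits)
  active_min <- sum(ev$capped_s[ev$countable]) / 60
  per_visit_min <- vapply(timeline$visits,
                          function(v) sum(v$capped_s[v$countable]) / 60,
                          numeric(1))
  platform <- ev$platform[!is.na(ev$platform)]
  data.frame(
    install_id = timeline$install_id,
    platform = if (length(platform)) platform[1L] else "unknown",
    license_accepted = timeline$accepted_license,
    n_visits = n_visits,
    n_events = sum(ev$countable),
    active_minutes = active_min,
    retention_weeks = floor((timeline$last_use_ms - timeline$first_use_ms) / MS_WEEK),
    level_achieved = if (length(lv)) max(lv, na.rm = TRUE) else 1L,
    mean_visit_minutes = mean(per_visit_min),
    first_use_ms = timeline$first_use_ms,
    last_use_ms = timeline$last_use_ms,
    category = as.character(categorize(n_visits)),
    stringsAsFactors = FALSE
  )
}

#' Engagement profiles for every installation in a sessionized stream
#'
#' Vectorized equivalent of [profile_user()] across all installations.
#'
#' @param sess a `sessionized` object from [sessionize_stream()].
#' @return data.frame, one row per installation, in install-id order.
#' @export
compute_profiles <- function(sess) {
  stopifnot(inherits(sess, "sessionized"))
  ev <- sess$events
  vs <- sess$visits
  ids <- unique(ev$install_id)  # already in sorted (stream) order
  if (!length(ids)) {
    return(data.frame(install_id = character(0), platform = character(0),
                      license_accepted = logical(0), n_visits = integer(0),
                      n_events = integer(0), active_minutes = numeric(0),
                      retention_weeks = numeric(0), level_achieved = integer(0),
                      mean_visit_minutes = numeric(0), first_use_ms = numeric(0),
                      last_use_ms = numeric(0), category = character(0),
                      stringsAsFactors = FALSE))
  }
  f <- factor(ev$install_id, levels = ids)
  fv <- factor(vs$install_id, levels = ids)
  lv_ev <- ev$event_name == "level_completed" & !is.na(ev$level)
  level_achieved <- rep(1L, length(ids))
  if (any(lv_ev)) {
    mx <- tapply(ev$level[lv_ev], factor(ev$install_id[lv_ev], levels = ids), max)
    level_achieved <- ifelse(is.na(mx), 1L, as.integer(mx))
  }
  plat <- tapply(ev$platform, f, function(p) {
    p <- p[!is.na(p)]
    if (length(p)) p[1L] else "unknown"
  })
  first_use <- as.numeric(tapply(ev$timestamp_ms, f, min))
  last_use <- as.numeric(tapply(ev$timestamp_ms, f, max))
  n_visits <- as.integer(tapply(vs$visit_index, fv, max))
  out <- data.frame(
    install_id = ids,
    platform = as.character(plat),
    license_accepted = as.logical(tapply(ev$event_name == "eula_accepted", f, any)),
    n_visits = n_visits,
    n_events = as.integer(tapply(ev$countable, f, sum)),
    active_minutes = as.numeric(tapply(ev$capped_s * ev$countable, f, sum)) / 60,
    retention_weeks = floor((last_use - first_use) / MS_WEEK),
    level_achieved = level_achieved,
    mean_visit_minutes = as.numeric(tapply(vs$active_seconds, fv, mean)) / 60,
    first_use_ms = first_use,
    last_use_ms = last_use,
    category = as.character(categorize(n_visits)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

profile_metrics <- c("level_achieved", "retention_weeks", "active_minutes",
                     "n_visits", "mean_visit_minutes", "n_events")

group_labels <- c(all = "all", exploratory = "1 visit", limited = "2-3 visits",
                  moderate = "4-7 visits", committed = "8+ visits")

split_profiles <- function(profiles) {
  groups <- c(list(all = profiles),
              split(profiles, factor(profiles$category, levels = CATEGORY_LEVELS)))
  keep <- vapply(groups, nrow, integer(1)) > 0L
  if (any(!keep)) {
    warning(sprintf("dropping empty group(s): %s",
                    paste(names(groups)[!keep], collapse = ", ")), call. = FALSE)
  }
  groups[keep]
}

#' Descriptive statistics of use variables by user category
#'
#' One row per group (all users plus the four visit-count bands) and metric,
#' with n, mean, SD and range, plus per-group license-acceptance and
#' platform counts.
#'
#' @param profiles profile table from [compute_profiles()].
#' @return list of class `descriptive_table`: `counts` (group sizes,
#'   license and platform splits with percentages) and `stats` (long table
#'   of mean/SD/min/max per group and metric).
#' @export
descriptive_table <- function(profiles) {
  if (!nrow(profiles)) stop("no profiles to summarize")
  groups <- split_profiles(profiles)
  counts <- do.call(rbind, lapply(names(groups), function(g) {
    p <- groups[[g]]
    n <- nrow(p)
    data.frame(
      group = group_labels[[g]], n = n,
      license_n = sum(p$license_accepted),
      license_pct = proportion_pct(sum(p$license_accepted), n),
      android_n = sum(p$platform == "android"),
      android_pct = proportion_pct(sum(p$platform == "android"), n),
      ios_n = sum(p$platform == "ios"),
      ios_pct = proportion_pct(sum(p$platform == "ios"), n),
      stringsAsFactors = FALSE
    )
  }))
  stats <- do.call(rbind, lapply(names(groups), function(g) {
    p <- groups[[g]]
    do.call(rbind, lapply(profile_metrics, function(m) {
      x <- p[[m]]
      data.frame(group = group_labels[[g]], metric = m, n = length(x),
                 mean = mean(x), sd = stats::sd(x),
                 min = min(x), max = max(x), stringsAsFactors = FALSE)
    }))
  }))
  rownames(counts) <- rownames(stats) <- NULL
  structure(list(counts = counts, stats = stats), class = "descriptive_table")
}

#' @method print descriptive_table
#' @export
print.descriptive_table <- function(x, ...) {
  cat("Group sizes:\n")
  print(x$counts, row.names = FALSE)
  cat("\nUse variables (mean / SD / range):\n")
  s <- x$stats
  s$mean <- round(s$mean, 1); s$sd <- round(s$sd, 1)
  print(s, row.names = FALSE)
  invisible(x)
}

#' Percentile distribution of use variables by user category
#'
#' Nearest-rank (type-1) percentiles of each engagement metric within each
#' user group.
#'
#' @param profiles profile table from [compute_profiles()].
#' @param probs percentile probabilities (default 25/50/75/90th).
#' @return long data.frame: group, metric, percentile, value.
#' @export
percentile_table <- function(profiles, probs = c(0.25, 0.5, 0.75, 0.9)) {
  if (!nrow(profiles)) stop("no profiles to summarize")
  groups <- split_profiles(profiles)
  out <- do.call(rbind, lapply(names(groups), function(g) {
    p <- groups[[g]]
    do.call(rbind, lapply(profile_metrics, function(m) {
      q <- stats::quantile(p[[m]], probs = probs, type = 1, names = FALSE)
      data.frame(group = group_labels[[g]], metric = m,
                 percentile = 100 * probs, value = q,
                 n = nrow(p), stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Return-use report
#'
#' For each window, the proportion of installations with any activity
#' strictly after `first_use + window`.  The denominator is every
#' installation.  Windows longer than the observation span are flagged as
#' censored: late installers cannot possibly show such a return.
#'
#' @param profiles profile table (uses `first_use_ms` / `last_use_ms`).
#' @param windows_days named vector of window lengths in days.
#' @param window_start_ms,window_end_ms observation-period bounds
#'   (epoch ms), used only for the censoring flag.
#' @return data.frame: window, days, numerator, denominator, pct, censored.
#' @export
return_use <- function(profiles, windows_days = DEFAULT_RETURN_WINDOWS,
                       window_start_ms = NULL, window_end_ms = NULL) {
  if (!nrow(profiles)) stop("no profiles")
  if (is.unsorted(windows_days)) stop("windows must be sorted ascending")
  denom <- nrow(profiles)
  span_ms <- if (!is.null(window_start_ms) && !is.null(window_end_ms)) {
    window_end_ms - window_start_ms
  } else max(profiles$last_use_ms) - min(profiles$first_use_ms)
  out <- do.call(rbind, lapply(seq_along(windows_days), function(i) {
    w <- windows_days[[i]]
    num <- sum(profiles$last_use_ms > profiles$first_use_ms + w * MS_DAY)
    data.frame(
      window = names(windows_days)[i] %||% as.character(w),
      days = w, numerator = num, denominator = denom,
      pct = proportion_pct(num, denom),
      censored = w * MS_DAY > span_ms,
      stringsAsFactors = FALSE
    )
  }))
  if (any(out$censored)) {
    warning("some windows exceed the observation span; their proportions are censored",
            call. = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Lint a retention report for internal consistency
#'
#' Checks that (a) each printed percentage equals the half-up two-decimal
#' percentage recomputed from its own numerator and denominator, and
#' (b) proportions are non-increasing as the window lengthens (a user
#' returning after 3 months necessarily returned after 1 month).  Useful for
#' auditing published retention tables as well as this package's output.
#'
#' @param report data.frame with columns `window`, `numerator`,
#'   `denominator`, `pct` (the printed percentage).
#' @return data.frame of flagged rows (`window`, `check`, `detail`);
#'   zero rows when the report is internally consistent.
#' @export
lint_retention <- function(report) {
  stopifnot(all(c("window", "numerator", "denominator", "pct") %in% names(report)))
  flags <- list()
  recomputed <- proportion_pct(report$numerator, report$denominator)
  bad <- abs(recomputed - report$pct) > 1e-9
  if (any(bad)) {
    flags[[length(flags) + 1L]] <- data.frame(
      window = report$window[bad], check = "count_percent_mismatch",
      detail = sprintf("printed %.2f%% but %d/%d = %.2f%%",
                       report$pct[bad], report$numerator[bad],
                       report$denominator[bad], recomputed[bad]),
      stringsAsFactors = FALSE
    )
  }
  if (nrow(report) > 1L) {
    inc <- which(diff(report$pct) > 1e-9) + 1L
    if (length(inc)) {
      flags[[length(flags) + 1L]] <- data.frame(
        window = report$window[inc], check = "monotonicity",
        detail = sprintf("%.2f%% exceeds the preceding window's %.2f%%",
                         report$pct[inc], report$pct[inc - 1L]),
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(flags)) {
    return(data.frame(window = character(0), check = character(0),
                      detail = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, flags)
  rownames(out) <- NULL
  out
}

#' Rolling retention: distinct active days, weeks and months
#'
#' Counts the distinct active days, weeks and months of use between initial
#' download and final use: the number of day-long, week-long (7-day) and
#' month-long (4-week) blocks since the installation's first use that
#' contain at least one countable event.  Anchoring the blocks at first use
#' makes the three granularities nest exactly (a day block lies in one week
#' block, a week block in one month block), so the counts always satisfy
#' days >= weeks >= months; calendar-aligned definitions cannot guarantee
#' that ordering at year and month boundaries.
#'
#' @param x a `user_timeline` (returns a named length-3 vector) or a
#'   `sessionized` object (returns a per-installation data.frame).
#' @return see above; a user with no countable events counts (0, 0, 0).
#' @export
rolling_retention <- function(x) {
  if (inherits(x, "user_timeline")) {
    ev <- do.call(rbind, x$visits)
    d <- floor((ev$timestamp_ms[ev$countable] - x$first_use_ms) / MS_DAY)
    return(c(days = length(unique(d)),
             weeks = length(unique(d %/% 7)),
             months = length(unique(d %/% 28))))
  }
  stopifnot(inherits(x, "sessionized"))
  ids <- unique(x$events$install_id)
  first_use <- tapply(x$events$timestamp_ms, factor(x$events$install_id, levels = ids), min)
  ev <- x$events[x$events$countable, , drop = FALSE]
  f <- factor(ev$install_id, levels = ids)
  d <- floor((ev$timestamp_ms - as.numeric(first_use[as.integer(f)])) / MS_DAY)
  cnt <- function(lab) {
    v <- tapply(lab, f, function(b) length(unique(b)))
    ifelse(is.na(v), 0L, as.integer(v))
  }
  data.frame(install_id = ids, active_days = cnt(d),
             active_weeks = cnt(d %/% 7), active_months = cnt(d %/% 28),
             stringsAsFactors = FALSE, row.names = NULL)
}
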