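# One-call orchestration: ingest -> sessionize -> profiles -> tables ->
# retention -> navigation -> FFMQ -> models -> report.  Each stage is
# wrapped so a failure is recorded and dependent stages are skipped with a
# reason; artifacts are plain CSV plus a Markdown report whose every
# percentage is recomputed from the adjacent counts.

#' Build a pipeline run configuration
#'
#' Collects and validates everything a full analysis run needs.  Exactly
#' one input source must be given: a JSON-lines log path, an in-memory
#' `event_stream`, or a `population_config` to simulate from.
#'
#' @param input path to a JSON-lines event log, or an `event_stream`.
#' @param simulate a [population_config()] to generate input from.
#' @param out_dir output directory (created if missing).
#' @param gap_minutes inactivity gap defining visits.
#' @param cap_minutes event-duration cap.
#' @param windows_days return-use windows (named days vector).
#' @param window_start,window_end observation window; defaults to the
#'   stream's own window.
#' @param ffmq_key_path optional YAML scoring key (default packaged key).
#' @param predictor_mode `"totals"` or `"cumulative"` engagement predictors.
#' @param time_degree,engagement_degree polynomial degrees for the model
#'   battery.
#' @param seed seed for simulation (and any resampling).
#' @param strict strict event-log validation.
#' @return list of class `run_config`.
#' @export
run_config <- function(input = NULL, simulate = NULL, out_dir = "mhengage-out",
                       gap_minutes = 30, cap_minutes = 30,
                       windows_days = DEFAULT_RETURN_WINDOWS,
                       window_start = NULL, window_end = NULL,
                       ffmq_key_path = NULL,
                       predictor_mode = c("totals", "cumulative"),
                       time_degree = 3L, engagement_degree = 1L,
                       seed = 1L, strict = FALSE) {
  predictor_mode <- match.arg(predictor_mode)
  n_sources <- (!is.null(input)) + (!is.null(simulate))
  if (n_sources != 1L) stop("give exactly one of `input` or `simulate`")
  if (is.character(input) && !file.exists(input)) {
    stop(sprintf("input log not found: %s", input))
  }
  if (!is.null(simulate) && !inherits(simulate, "population_config")) {
    stop("`simulate` must be a population_config")
  }
  if (!is.null(ffmq_key_path) && !file.exists(ffmq_key_path)) {
    stop(sprintf("FFMQ key not found: %s", ffmq_key_path))
  }
  if (gap_minutes <= 0 || cap_minutes <= 0) {
    stop("gap_minutes and cap_minutes must be positive")
  }
  if (!is.null(window_start) && !is.null(window_end) &&
      posix_to_ms(window_start) >= posix_to_ms(window_end)) {
    stop("window_start must precede window_end")
  }
  structure(list(
    input = input, simulate = simulate, out_dir = out_dir,
    gap_minutes = gap_minutes, cap_minutes = cap_minutes,
    windows_days = windows_days, window_start = window_start,
    window_end = window_end, ffmq_key_path = ffmq_key_path,
    predictor_mode = predictor_mode, time_degree = time_degree,
    engagement_degree = engagement_degree, seed = seed, strict = strict
  ), class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Reads the fields of [run_config()] from a YAML file; a `simulate` block
#' is passed to [population_config()].
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
run_config_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$simulate)) {
    raw$simulate <- do.call(population_config, raw$simulate)
  }
  do.call(run_config, raw)
}

write_csv_out <- function(df, out_dir, name) {
  path <- file.path(out_dir, name)
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes every stage and writes nine artifacts to `out_dir`:
#' `visits.csv`, `profiles.csv`, `table1.csv` (descriptives by user group),
#' `table2.csv` (percentiles), `retention.csv`, `table3.csv` (navigation),
#' `ffmq_scores.csv`, `models.csv` and `report.md`.  Identical
#' configuration and input produce byte-identical CSVs.  A failed stage is
#' logged with its error; stages depending on it are skipped with a reason,
#' and the run is marked unsuccessful.
#'
#' @param config a [run_config()] (or path to its YAML form).
#' @return invisibly, list with `status` (stage, ok, skipped, error,
#'   seconds), `artifacts` (paths written), `ok` (overall flag), and the
#'   in-memory stage results.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- run_config_yaml(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- new.env(parent = emptyenv())
  status <- list()
  artifacts <- character(0)

  stage <- function(name, needs, fun) {
    missing_dep <- needs[!vapply(needs, function(d) isTRUE(res[[paste0(".ok.", d)]]),
                                 logical(1))]
    t0 <- proc.time()[["elapsed"]]
    if (length(missing_dep)) {
      message(sprintf("[%s] skipped (requires: %s)", name,
                      paste(missing_dep, collapse = ", ")))
      status[[name]] <<- data.frame(stage = name, ok = FALSE, skipped = TRUE,
                                    error = sprintf("upstream stage failed: %s",
                                                    paste(missing_dep, collapse = ", ")),
                                    seconds = 0, stringsAsFactors = FALSE)
      return(invisible(NULL))
    }
    out <- tryCatch(list(value = fun()), error = function(e) e)
    el <- proc.time()[["elapsed"]] - t0
    if (inherits(out, "error")) {
      message(sprintf("[%s] FAILED: %s", name, conditionMessage(out)))
      status[[name]] <<- data.frame(stage = name, ok = FALSE, skipped = FALSE,
                                    error = conditionMessage(out), seconds = el,
                                    stringsAsFactors = FALSE)
    } else {
      message(sprintf("[%s] done in %.1fs", name, el))
      res[[name]] <- out$value
      res[[paste0(".ok.", name)]] <- TRUE
      status[[name]] <<- data.frame(stage = name, ok = TRUE, skipped = FALSE,
                                    error = NA_character_, seconds = el,
                                    stringsAsFactors = FALSE)
    }
    invisible(NULL)
  }

  stage("ingest", character(0), function() {
    s <- if (!is.null(config$simulate)) {
      generate_population(config$simulate, seed = config$seed)$stream
    } else if (inherits(config$input, "event_stream")) {
      config$input
    } else {
      read_event_log(config$input, strict = config$strict,
                     window_start = config$window_start,
                     window_end = config$window_end)
    }
    if (nrow(s$records) == 0L) stop("input contains no valid event records")
    s
  })

  stage("sessionize", "ingest", function() {
    sess <- sessionize_stream(res$ingest, gap_s = config$gap_minutes * 60,
                              cap_s = config$cap_minutes * 60)
    nav <- visit_navigation(sess)
    v <- nav$visits
    v$active_minutes <- round(v$active_seconds / 60, 4)
    artifacts <<- c(artifacts, write_csv_out(
      v[, c("install_id", "visit_index", "start_ms", "end_ms", "n_records",
            "n_events", "active_minutes", "session_type", "first_area",
            "n_distinct")],
      config$out_dir, "visits.csv"))
    sess
  })

  stage("profiles", "sessionize", function() {
    p <- compute_profiles(res$sessionize)
    artifacts <<- c(artifacts, write_csv_out(p, config$out_dir, "profiles.csv"))
    p
  })

  stage("tables", "profiles", function() {
    d <- descriptive_table(res$profiles)
    t1 <- merge(d$counts, d$stats[setdiff(names(d$stats), "n")],
                by = "group", sort = FALSE)
    artifacts <<- c(artifacts, write_csv_out(t1, config$out_dir, "table1.csv"))
    t2 <- percentile_table(res$profiles)
    artifacts <<- c(artifacts, write_csv_out(t2, config$out_dir, "table2.csv"))
    list(table1 = d, table2 = t2)
  })

  stage("retention", "profiles", function() {
    s <- res$ingest
    rep_ <- return_use(res$profiles, windows_days = config$windows_days,
                       window_start_ms = s$window_start_ms,
                       window_end_ms = s$window_end_ms)
    flags <- lint_retention(rep_)
    if (nrow(flags)) {
      warning(sprintf("retention report failed internal consistency: %s",
                      paste(flags$detail, collapse = " | ")), call. = FALSE)
    }
    roll <- rolling_retention(res$sessionize)
    out <- rep_
    artifacts <<- c(artifacts, write_csv_out(out, config$out_dir, "retention.csv"))
    list(return_use = rep_, rolling = roll, flags = flags)
  })

  stage("navigation", "sessionize", function() {
    nav <- navigation_summary(res$sessionize)
    t3 <- merge(nav$panels, nav$tests, by = "panel", sort = FALSE)
    artifacts <<- c(artifacts, write_csv_out(t3, config$out_dir, "table3.csv"))
    nav
  })

  stage("ffmq", "sessionize", function() {
    key <- if (is.null(config$ffmq_key_path)) ffmq_key() else ffmq_key(config$ffmq_key_path)
    sc <- extract_assessments(res$sessionize, key = key)
    artifacts <<- c(artifacts, write_csv_out(as.data.frame(sc), config$out_dir,
                                             "ffmq_scores.csv"))
    sc
  })

  stage("models", c("ffmq", "profiles"), function() {
    if (nrow(res$ffmq) == 0L) stop("no scored assessment occasions")
    tab <- assemble_long_table(res$ffmq, res$profiles,
                               mode = config$predictor_mode,
                               sess = res$sessionize)
    bat <- fit_battery(tab, time_degree = config$time_degree,
                       engagement_degree = config$engagement_degree)
    artifacts <<- c(artifacts, write_csv_out(bat$results, config$out_dir,
                                             "models.csv"))
    list(table = tab, battery = bat)
  })

  stage("report", c("profiles", "retention", "navigation"), function() {
    path <- file.path(config$out_dir, "report.md")
    writeLines(render_report(res, config), path)
    artifacts <<- c(artifacts, path)
    path
  })

  status <- do.call(rbind, status)
  rownames(status) <- NULL
  ok <- all(status$ok)
  if (!ok) {
    message("pipeline finished with failed stage(s): ",
            paste(status$stage[!status$ok], collapse = ", "))
  }
  invisible(list(status = status, artifacts = artifacts, ok = ok,
                 results = as.list(res)))
}

# Markdown report: every percentage is proportion_pct() of counts that are
# printed right beside it.
render_report <- function(res, config) {
  p <- res$profiles
  n <- nrow(p)
  pct <- function(k) sprintf("%.2f%% (%s/%s)", proportion_pct(k, n),
                             format(k, big.mark = ","), format(n, big.mark = ","))
  lines <- c(
    "# Engagement analytics report", "",
    sprintf("Installations analysed: %s", format(n, big.mark = ",")),
    sprintf("- Android: %s; iOS: %s", pct(sum(p$platform == "android")),
            pct(sum(p$platform == "ios"))),
    sprintf("- License accepted: %s", pct(sum(p$license_accepted))), "",
    "## User categories", ""
  )
  for (cg in CATEGORY_LEVELS) {
    lines <- c(lines, sprintf("- %s (%s): %s", cg, group_labels[[cg]],
                              pct(sum(p$category == cg))))
  }
  lines <- c(lines, "", "## Return use", "",
             "| window | returned | of | % |", "|---|---|---|---|")
  ru <- res$retention$return_use
  lines <- c(lines, sprintf("| %s | %d | %d | %.2f |", ru$window, ru$numerator,
                            ru$denominator, proportion_pct(ru$numerator, ru$denominator)))
  fl <- res$retention$flags
  lines <- c(lines, "",
             if (nrow(fl)) sprintf("Consistency flags: %s",
                                   paste(fl$detail, collapse = "; "))
             else "Internal consistency checks passed (percentages recompute from counts; proportions non-increasing).")
  fa <- res$navigation$panels
  fa <- fa[fa$panel == "first_area" & fa$session_type == "first_time", ]
  fa <- fa[order(-fa$count), ]
  lines <- c(lines, "", "## First content area (first-time sessions)", "")
  lines <- c(lines, sprintf("- %s: %.2f%% (%d/%d)", fa$label,
                            proportion_pct(fa$count, fa$denominator),
                            fa$count, fa$denominator))
  if (!is.null(res$models)) {
    r2 <- unique(res$models$battery$results[, c("outcome", "predictor", "r_squared")])
    r2 <- r2[!is.na(r2$r_squared), ]
    lines <- c(lines, "", "## Model battery (marginal pseudo-R^2)", "",
               sprintf("- %s ~ %s: R^2 = %.3f", r2$outcome, r2$predictor,
                       r2$r_squared))
  }
  lines
}
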