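# Synthetic telemetry generator: produces event logs with the statistical
# structure the analysis pipeline assumes -- a four-category user mixture
# with heavy right-skew in visits and events, a license-acceptance first
# event, within-visit gaps strictly below and between-visit gaps at or above
# the 30-minute boundary (so sessionization recovers the intended visit
# counts by construction), content-area navigation resembling the observed
# first-area frequencies, level progression 1-14, and FFMQ-SF responses
# whose occasion totals follow a known outcome model.  Every generated
# dataset carries its ground truth, so estimators can be validated by
# parameter recovery.

#' Population configuration for the synthetic generator
#'
#' Builds the full parameter set with defaults that emulate the published
#' engagement distributions: category mix 39/32/18/11 (exploratory /
#' limited / moderate / committed), 62.9\% Android, 87.8\% license
#' acceptance, committed visit counts from a shifted negative binomial
#' capped at 506, log-normal inter-visit gaps and event durations, stylized
#' first-content-area frequencies per session type, a 10\% per-visit level
#' hazard, assessment prompts at levels 1/7/14, and an FFMQ-SF outcome model
#' `total = b0 + b1 * g(engagement) + u + e` with normal user and occasion
#' noise.  All distributions are swappable through the arguments.
#'
#' @param n_users number of installations.
#' @param category_mix probabilities over the four engagement categories.
#' @param platform_mix probabilities for android/ios.
#' @param p_license probability the first visit accepts the license.
#' @param committed_nb size/mu of the negative binomial added to 8 visits
#'   for committed users.
#' @param visits_max hard cap on visits per user.
#' @param intervisit_gap_days meanlog/sdlog of the log-normal gap between
#'   consecutive visits, in days (floored at just over 30 minutes).
#' @param events_per_visit meanlog/sdlog of the log-normal filler-event
#'   count per visit.
#' @param event_gap_s meanlog/sdlog of within-visit inter-event gaps in
#'   seconds (clamped to `[1, 1700]`, keeping visits intact).
#' @param event_duration_s meanlog/sdlog of screen/filler durations (s).
#' @param zero_duration_prob probability a screen/filler record has zero
#'   duration (a click in time: anchors boundaries, not counted as an
#'   event).
#' @param p_home_only per session type, probability a visit never leaves
#'   the home screen.
#' @param first_area_probs,extra_area_probs per session type, label
#'   probabilities for the first / subsequent content-area entries.
#' @param extra_entry_geom_p geometric parameter for extra area entries.
#' @param p_level per-visit probability of completing the next level.
#' @param p_comply compliance probabilities for the level-1/7/14 prompts.
#' @param p_spontaneous per-visit probability of an unprompted assessment.
#' @param p_abandon probability a started assessment is abandoned.
#' @param outcome list: `predictor` (`"log_active_minutes"`,
#'   `"active_minutes"` or `"weeks_since_install"`), `beta` (raw polynomial
#'   coefficients, intercept first), `tau` (user SD), `sigma` (occasion SD).
#' @param window_start,window_end observation window (UTC).
#' @return list of class `population_config`.
#' @export
population_config <- function(
    n_users = 1000L,
    category_mix = c(exploratory = 0.39, limited = 0.32,
                     moderate = 0.18, committed = 0.11),
    platform_mix = c(android = 0.629, ios = 0.371),
    p_license = 0.878,
    committed_nb = list(size = 1.2, mu = 11.3),
    visits_max = 506L,
    intervisit_gap_days = list(meanlog = 0.63, sdlog = 1.4),
    events_per_visit = list(meanlog = 1.9, sdlog = 0.9),
    event_gap_s = list(meanlog = 3.0, sdlog = 0.8),
    event_duration_s = list(meanlog = 2.5, sdlog = 1.0),
    zero_duration_prob = 0.2,
    p_home_only = c(first_time = 0.2974, return = 0.3836),
    first_area_probs = list(
      first_time = c(training_plan = 0.6323, practice_now = 0.2303,
                     build_expertise = 0.0431, track_progress = 0.0235,
                     badges = 0.0079, other = 0.0628),
      return = c(training_plan = 0.4255, practice_now = 0.4569,
                 build_expertise = 0.0456, track_progress = 0.0510,
                 badges = 0.0068, other = 0.0141)
    ),
    extra_area_probs = list(
      first_time = c(training_plan = 0.4931, practice_now = 0.2712,
                     build_expertise = 0.0863, track_progress = 0.0716,
                     badges = 0.0138, other = 0.0641),
      return = c(training_plan = 0.3727, practice_now = 0.4243,
                 build_expertise = 0.0796, track_progress = 0.0878,
                 badges = 0.0125, other = 0.0231)
    ),
    extra_entry_geom_p = 0.5,
    p_level = 0.10,
    p_comply = c(0.35, 0.6, 0.7),
    p_spontaneous = 0.05,
    p_abandon = 0.15,
    outcome = list(predictor = "log_active_minutes",
                   beta = c(50, 2.5), tau = 6, sigma = 6),
    window_start = "2018-08-01", window_end = "2019-04-08") {
  cfg <- as.list(environment())
  errs <- character(0)
  chk_prob_vec <- function(p, nm) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-6) {
      errs <<- c(errs, sprintf("%s must be nonnegative and sum to 1", nm))
    }
  }
  chk_prob_vec(category_mix, "category_mix")
  chk_prob_vec(platform_mix, "platform_mix")
  for (st in c("first_time", "return")) {
    chk_prob_vec(first_area_probs[[st]] / sum(first_area_probs[[st]]),
                 paste0("first_area_probs$", st))
  }
  if (n_users < 0) errs <- c(errs, "n_users must be nonnegative")
  for (nm in c("p_license", "zero_duration_prob", "p_level",
               "p_spontaneous", "p_abandon", "extra_entry_geom_p")) {
    v <- cfg[[nm]]
    if (v < 0 || v > 1) errs <- c(errs, sprintf("%s must be in [0,1]", nm))
  }
  if (any(p_comply < 0 | p_comply > 1) || length(p_comply) != 3L) {
    errs <- c(errs, "p_comply must be three probabilities")
  }
  for (nm in c("committed_nb", "intervisit_gap_days", "events_per_visit",
               "event_gap_s", "event_duration_s")) {
    sc <- cfg[[nm]]
    if (any(unlist(sc[names(sc) %in% c("size", "mu", "sdlog")]) <= 0)) {
      errs <- c(errs, sprintf("%s scale parameters must be positive", nm))
    }
  }
  if (!outcome$predictor %in% c("log_active_minutes", "active_minutes",
                                "weeks_since_install")) {
    errs <- c(errs, "outcome$predictor unknown")
  }
  if (length(outcome$beta) < 1L || length(outcome$beta) > 4L) {
    errs <- c(errs, "outcome$beta must have 1-4 coefficients")
  }
  if (outcome$tau < 0 || outcome$sigma < 0) {
    errs <- c(errs, "outcome tau and sigma must be nonnegative")
  }
  if (posix_to_ms(window_start) >= posix_to_ms(window_end)) {
    errs <- c(errs, "window_start must precede window_end")
  }
  if (length(errs)) stop(paste(errs, collapse = "; "))
  # normalize the navigation probability vectors
  cfg$first_area_probs <- lapply(first_area_probs, function(p) p / sum(p))
  cfg$extra_area_probs <- lapply(extra_area_probs, function(p) p / sum(p))
  structure(cfg, class = "population_config")
}

#' @method print population_config
#' @export
print.population_config <- function(x, ...) {
  cat(sprintf("<population_config> %d users, mix %s, outcome %s deg %d (tau %.1f, sigma %.1f)\n",
              x$n_users,
              paste(sprintf("%.2f", x$category_mix), collapse = "/"),
              x$outcome$predictor, length(x$outcome$beta) - 1L,
              x$outcome$tau, x$outcome$sigma))
  invisible(x)
}

# Occasion placement rules for one visit-level table: prompted at the
# level-1 (first) visit and at the visits reaching levels 7 and 14, each
# with its compliance probability, plus a per-visit spontaneous chance.
# Licensed users only.  Returns occasion/abandon flags and the trigger.
place_occasions <- function(is_first_v, new_level, licensed_v, config) {
  V <- length(is_first_v)
  lvl7 <- !is.na(new_level) & new_level == 7L
  lvl14 <- !is.na(new_level) & new_level == 14L
  t1 <- is_first_v & stats::rbinom(V, 1L, config$p_comply[1]) == 1L
  t7 <- lvl7 & stats::rbinom(V, 1L, config$p_comply[2]) == 1L
  t14 <- lvl14 & stats::rbinom(V, 1L, config$p_comply[3]) == 1L
  sp <- stats::rbinom(V, 1L, config$p_spontaneous) == 1L
  occ <- licensed_v & (t1 | t7 | t14 | sp)
  trigger <- rep(NA_character_, V)
  trigger[occ & sp] <- "spontaneous"
  trigger[occ & t14] <- "prompt_level14"
  trigger[occ & t7] <- "prompt_level7"
  trigger[occ & t1] <- "prompt_level1"
  abandon <- occ & stats::rbinom(V, 1L, config$p_abandon) == 1L
  list(occasion = occ, abandon = abandon, trigger = trigger)
}

#' Place assessment occasions for one user
#'
#' Applies the prompting rules (levels 1, 7 and 14 with per-prompt
#' compliance, plus spontaneous per-visit assessments and abandonment) to a
#' single user's visit sequence.  Uses the current RNG state.
#'
#' @param n_visits number of visits.
#' @param new_level per-visit level reached by a completion in that visit
#'   (`NA` for visits without one).
#' @param config a `population_config`.
#' @param licensed did this user accept the license?
#' @return data.frame with one row per visit holding an occasion: columns
#'   `visit_index`, `trigger`, `abandoned`.
#' @export
generate_ffmq_occasions <- function(n_visits, new_level = rep(NA_integer_, n_visits),
                                    config = population_config(),
                                    licensed = TRUE) {
  stopifnot(length(new_level) == n_visits)
  pl <- place_occasions(seq_len(n_visits) == 1L, new_level,
                        rep(licensed, n_visits), config)
  data.frame(visit_index = which(pl$occasion),
             trigger = pl$trigger[pl$occasion],
             abandoned = pl$abandon[pl$occasion],
             stringsAsFactors = FALSE)
}

# Decompose integer totals (19-95) into a 19 x K matrix of scored item
# values in [1,5] summing (exactly) to the target, with one random
# redistribution pass so items are not perfectly uniform.
decompose_totals <- function(totals, n_items = 19L) {
  K <- length(totals)
  if (!K) return(matrix(numeric(0), n_items, 0))
  m <- totals %/% n_items
  r <- totals %% n_items
  S <- matrix(rep(m, each = n_items), n_items, K)
  # +1 on r randomly chosen items per occasion
  U <- matrix(stats::runif(n_items * K), n_items, K)
  rk <- apply(U, 2L, rank, ties.method = "first")
  S <- S + (rk <= rep(r, each = n_items))
  # one redistribution pass: move a point between two random items where
  # bounds allow, preserving the column total
  i1 <- sample.int(n_items, K, replace = TRUE)
  i2 <- sample.int(n_items, K, replace = TRUE)
  ok <- i1 != i2
  a <- cbind(i1, seq_len(K)); b <- cbind(i2, seq_len(K))
  ok <- ok & S[a] < 5 & S[b] > 1
  S[a[ok, , drop = FALSE]] <- S[a[ok, , drop = FALSE]] + 1
  S[b[ok, , drop = FALSE]] <- S[b[ok, , drop = FALSE]] - 1
  S
}

# Vectorized core: build the full event table for given per-user categories.
# Does not seed the RNG; generate_population() does.
generate_core <- function(categories, config) {
  n <- length(categories)
  ws <- posix_to_ms(config$window_start)
  we <- posix_to_ms(config$window_end)
  key <- ffmq_key()
  if (n == 0L) {
    stream <- event_stream(empty_records(), source = "synthetic",
                           window_start = ws, window_end = we)
    return(list(stream = stream,
                truth = list(users = data.frame(), occasions = data.frame(),
                             params = config$outcome)))
  }
  install_ids <- sprintf("u%06d", seq_len(n))
  platform <- sample(names(config$platform_mix), n, TRUE, config$platform_mix)
  licensed <- stats::rbinom(n, 1L, config$p_license) == 1L

  nv <- integer(n)
  nv[categories == "exploratory"] <- 1L
  nv[categories == "limited"] <- sample(2:3, sum(categories == "limited"), TRUE)
  nv[categories == "moderate"] <- sample(4:7, sum(categories == "moderate"), TRUE)
  ncom <- sum(categories == "committed")
  nv[categories == "committed"] <- as.integer(pmin(
    8L + stats::rnbinom(ncom, size = config$committed_nb$size,
                        mu = config$committed_nb$mu),
    config$visits_max))

  # ---- visit level ----
  uidx <- rep(seq_len(n), nv)
  vseq <- sequence(nv)
  V <- length(uidx)
  licensed_v <- licensed[uidx]
  is_first_v <- vseq == 1L
  stype_v <- ifelse(is_first_v & licensed_v, "first_time", "return")

  home_only <- stats::rbinom(V, 1L, config$p_home_only[stype_v]) == 1L
  n_area <- ifelse(home_only, 0L,
                   1L + pmin(stats::rgeom(V, config$extra_entry_geom_p), 14L))
  n_filler <- pmin(200L, pmax(0L, round(stats::rlnorm(
    V, config$events_per_visit$meanlog, config$events_per_visit$sdlog))))
  lv_draw <- licensed_v & stats::rbinom(V, 1L, config$p_level) == 1L
  cum_lv <- group_cumsum(as.numeric(lv_draw), uidx)
  emit_level <- lv_draw & cum_lv <= 13
  new_level <- ifelse(emit_level, 1L + cum_lv, NA_integer_)

  pl <- place_occasions(is_first_v, new_level, licensed_v, config)
  occ <- pl$occasion; abandon <- pl$abandon
  n_ab_items <- sample(5:12, V, replace = TRUE)
  n_items <- ifelse(occ & !abandon, 19L, ifelse(occ, n_ab_items, 0L))
  n_done <- as.integer(occ & !abandon)

  # ---- event-level expansion ----
  # component order within a visit: launch, eula, home screen, area
  # entries, filler interactions, level completion, assessment run
  comp_counts <- list(
    launch = rep(1L, V),
    eula = as.integer(is_first_v & licensed_v),
    home = rep(1L, V),
    area = as.integer(n_area),
    filler = as.integer(n_filler),
    level = as.integer(emit_level),
    item = as.integer(n_items),
    done = n_done
  )
  comp_rank <- stats::setNames(seq_along(comp_counts), names(comp_counts))
  ev_list <- lapply(names(comp_counts), function(cp) {
    cnt <- comp_counts[[cp]]
    vr <- rep.int(seq_len(V), cnt)
    data.frame(vrow = vr, comp = rep.int(comp_rank[[cp]], length(vr)),
               k = sequence(cnt))
  })
  ev <- do.call(rbind, ev_list)
  ev <- ev[order(ev$vrow, ev$comp, ev$k, method = "radix"), , drop = FALSE]
  E <- nrow(ev)
  comp <- ev$comp
  vrow <- ev$vrow

  # inter-event gaps (seconds), by component; first event of a visit at 0
  gap_s <- numeric(E)
  scr <- comp %in% comp_rank[c("eula", "home", "area", "filler", "level")]
  gap_s[scr] <- pmin(1700, pmax(1, stats::rlnorm(
    sum(scr), config$event_gap_s$meanlog, config$event_gap_s$sdlog)))
  it <- comp == comp_rank[["item"]]
  gap_s[it] <- stats::runif(sum(it), 2, 10)
  dn <- comp == comp_rank[["done"]]
  gap_s[dn] <- stats::runif(sum(dn), 1, 3)
  first_of_visit <- !duplicated(vrow)
  gap_s[first_of_visit] <- 0
  offset_ms <- round(group_cumsum(gap_s, vrow) * 1000)

  # durations (seconds), by component; a share of screen/filler records are
  # zero-duration clicks
  dur <- numeric(E)
  dur[comp == comp_rank[["launch"]]] <- stats::runif(sum(comp == comp_rank[["launch"]]), 2, 10)
  dur[comp == comp_rank[["eula"]]] <- stats::runif(sum(comp == comp_rank[["eula"]]), 5, 30)
  scrn <- comp %in% comp_rank[c("home", "area", "filler")]
  dur[scrn] <- stats::rlnorm(sum(scrn), config$event_duration_s$meanlog,
                             config$event_duration_s$sdlog)
  dur[scrn][stats::runif(sum(scrn)) < config$zero_duration_prob] <- 0
  dur[comp == comp_rank[["level"]]] <- stats::runif(sum(comp == comp_rank[["level"]]), 1, 3)
  dur[it] <- stats::runif(sum(it), 2, 6)
  dur[dn] <- stats::runif(sum(dn), 1, 3)
  dur <- round(dur, 1)

  # event names and content areas
  event_name <- character(E)
  event_name[comp == comp_rank[["launch"]]] <- "launch"
  event_name[comp == comp_rank[["eula"]]] <- "eula_accepted"
  event_name[comp == comp_rank[["home"]]] <- "screen_view"
  event_name[comp == comp_rank[["area"]]] <- "screen_view"
  event_name[comp == comp_rank[["level"]]] <- "level_completed"
  event_name[it] <- "assessment_item"
  event_name[dn] <- "assessment_completed"
  fl <- comp == comp_rank[["filler"]]
  event_name[fl] <- ifelse(stats::runif(sum(fl)) < 0.3, "exercise_started", "other")

  content_area <- rep(NA_character_, E)
  content_area[comp == comp_rank[["home"]]] <- "home"
  ar <- comp == comp_rank[["area"]]
  if (any(ar)) {
    ar_first <- ar & ev$k == 1L
    ar_extra <- ar & ev$k > 1L
    for (st in c("first_time", "return")) {
      sel <- ar_first & stype_v[vrow] == st
      if (any(sel)) {
        content_area[sel] <- sample(names(config$first_area_probs[[st]]),
                                    sum(sel), TRUE, config$first_area_probs[[st]])
      }
      sel <- ar_extra & stype_v[vrow] == st
      if (any(sel)) {
        content_area[sel] <- sample(names(config$extra_area_probs[[st]]),
                                    sum(sel), TRUE, config$extra_area_probs[[st]])
      }
    }
  }

  level_payload <- rep(NA_integer_, E)
  level_payload[comp == comp_rank[["level"]]] <- new_level[emit_level]
  platform_payload <- rep(NA_character_, E)
  launch1 <- comp == comp_rank[["launch"]] & is_first_v[vrow]
  platform_payload[launch1] <- platform[uidx[vrow[launch1]]]

  # ---- visit start times, fitted into the observation window ----
  D <- numeric(V)  # within-visit span (ms)
  last_of_visit <- !duplicated(vrow, fromLast = TRUE)
  D[vrow[last_of_visit]] <- offset_ms[last_of_visit]
  g <- numeric(V)  # gap from previous visit's end (ms), >= 30 min + 1 s
  g[!is_first_v] <- pmax(1801000, stats::rlnorm(
    sum(!is_first_v), config$intervisit_gap_days$meanlog,
    config$intervisit_gap_days$sdlog) * MS_DAY)

  install <- ws + stats::runif(n) * (we - MS_DAY - ws)
  margin <- 60000
  sumD <- as.numeric(rowsum(D, uidx)[, 1L])
  sumG <- as.numeric(rowsum(g, uidx)[, 1L])
  gmin_tot <- (nv - 1L) * 1801000
  # shift late installers back so even minimal spacing fits the window
  install <- pmin(install, we - margin - sumD - gmin_tot)
  if (any(install < ws)) stop("observation window too short for configured visit counts")
  avail <- we - margin - install - sumD
  over <- sumG > avail & nv > 1L
  if (any(over)) {
    # compress this user's gaps onto [gmin, avail], preserving proportions
    w <- ifelse(is_first_v, 0, pmax(0, g - 1801000))
    sumW <- as.numeric(rowsum(w, uidx)[, 1L])
    ou <- over[uidx] & !is_first_v
    wu <- ifelse(sumW[uidx] > 0, w / pmax(sumW[uidx], 1), 1 / pmax(nv[uidx] - 1L, 1))
    g[ou] <- 1801000 + (avail - gmin_tot)[uidx][ou] * wu[ou]
  }
  lagD <- c(0, D[-V]); lagD[is_first_v] <- 0
  step <- ifelse(is_first_v, 0, lagD + g)
  visit_start <- round(install[uidx] + group_cumsum(step, uidx))

  ts <- visit_start[vrow] + offset_ms

  # ---- realized engagement and the outcome model ----
  countable <- dur > 0
  capped <- pmin(dur, 1800)
  act_sec <- rep(0, n)
  as_agg <- rowsum((capped * countable), uidx[vrow])
  act_sec[as.integer(rownames(as_agg))] <- as_agg[, 1L]
  active_minutes <- act_sec / 60
  level_achieved <- rep(1L, n)
  if (any(emit_level)) {
    la <- tapply(new_level[emit_level], uidx[emit_level], max)
    level_achieved[as.integer(names(la))] <- as.integer(la)
  }

  u_user <- stats::rnorm(n, 0, config$outcome$tau)
  done_rows <- which(dn)
  occ_vrow <- vrow[done_rows]          # visit row of each completed occasion
  occ_user <- uidx[occ_vrow]
  occ_ts <- ts[done_rows]
  occ_weeks <- (occ_ts - install[occ_user]) / MS_WEEK
  beta <- config$outcome$beta
  mu <- switch(config$outcome$predictor,
    log_active_minutes = beta[1] + beta[2] * log1p(active_minutes[occ_user]),
    active_minutes = beta[1] + beta[2] * active_minutes[occ_user],
    weeks_since_install =
      drop(outer(occ_weeks, seq_along(beta) - 1L, `^`) %*% beta)
  )
  latent <- mu + u_user[occ_user] + stats::rnorm(length(mu), 0, config$outcome$sigma)
  realized <- pmin(95, pmax(19, round(latent)))

  # scored item matrix -> raw responses (reverse-scored items flipped)
  S <- decompose_totals(realized)
  rev_pos <- key$items %in% key$reverse
  R <- S
  R[rev_pos, ] <- 6 - R[rev_pos, ]

  item_id <- rep(NA_character_, E)
  response <- rep(NA_integer_, E)
  complete_v <- occ & !abandon
  it_complete <- it & complete_v[vrow]
  item_id[it_complete] <- key$items[ev$k[it_complete]]
  response[it_complete] <- as.integer(R)  # column-major matches event order
  it_ab <- it & !complete_v[vrow]
  item_id[it_ab] <- key$items[ev$k[it_ab]]
  response[it_ab] <- sample(1:5, sum(it_ab), replace = TRUE)

  records <- data.frame(
    install_id = install_ids[uidx[vrow]],
    timestamp_ms = ts,
    event_name = event_name,
    content_area = content_area,
    duration_s = dur,
    level = level_payload,
    item = item_id,
    response = response,
    platform = platform_payload,
    cap_s = NA_real_,
    stringsAsFactors = FALSE
  )
  stream <- event_stream(records, source = "synthetic",
                         window_start = ws, window_end = we)

  truth <- list(
    users = data.frame(
      install_id = install_ids, category = categories, platform = platform,
      licensed = licensed, n_visits = nv, active_minutes = active_minutes,
      level_achieved = level_achieved, u = u_user,
      install_ms = round(install), stringsAsFactors = FALSE
    ),
    occasions = data.frame(
      install_id = install_ids[occ_user], timestamp_ms = occ_ts,
      weeks_since_install = occ_weeks, latent_total = latent,
      realized_total = as.numeric(realized), stringsAsFactors = FALSE
    ),
    n_abandoned = sum(abandon),
    params = config$outcome
  )
  list(stream = stream, truth = truth)
}

#' Generate a synthetic population event log
#'
#' Draws a population from a `population_config` and emits a validated,
#' sorted event stream plus the ground truth behind it.  Deterministic
#' given the seed (Mersenne-Twister): the same seed yields byte-identical
#' logs.
#'
#' @param config a [population_config()].
#' @param seed integer seed.
#' @return list with `stream` (an `event_stream`) and `truth` (per-user
#'   categories and realized engagement, per-occasion latent and realized
#'   FFMQ-SF totals, the outcome-model parameters, abandonment count).
#' @export
generate_population <- function(config = population_config(), seed = 1L) {
  stopifnot(inherits(config, "population_config"))
  set.seed(seed, kind = "Mersenne-Twister")
  n <- config$n_users
  categories <- if (n > 0) {
    sample(names(config$category_mix), n, TRUE, config$category_mix)
  } else character(0)
  out <- generate_core(categories, config)
  out$truth$seed <- seed
  out
}

#' Generate events for a single user of known category
#'
#' Runs the generator core for one user with a fixed engagement category,
#' using the current RNG state.  Mainly useful for focused tests: an
#' exploratory user always yields exactly one visit, a committed user at
#' least eight.
#'
#' @param category engagement category.
#' @param config a [population_config()].
#' @return list with `stream` and `truth` as in [generate_population()].
#' @export
generate_user <- function(category = c("exploratory", "limited", "moderate",
                                       "committed"),
                          config = population_config()) {
  category <- match.arg(category)
  generate_core(category, config)
}
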