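# Profiles, categories, two-stage means, descriptive/percentile tables,
# return use, rolling retention, printed-percentage arithmetic.

test_that("profile_user aggregates a timeline correctly", {
  # 1 visit, 8 countable events totalling 240 s
  ev <- fix_events("u1", seq(0, 70, by = 10), duration_s = 30)
  tl <- build_timeline(fix_stream(ev), "u1")
  p <- profile_user(tl)
  expect_identical(p$n_visits, 1L)
  expect_identical(p$n_events, 8L)
  expect_identical(p$active_minutes, 4)
  expect_identical(p$retention_weeks, 0)
  expect_identical(p$level_achieved, 1L)  # no level_completed events
  expect_identical(p$category, "exploratory")
})

test_that("retention weeks floor elapsed days over seven", {
  ev <- rbind(fix_events("u1", 0), fix_events("u1", 20 * 86400))
  p <- profile_user(build_timeline(fix_stream(ev), "u1"))
  expect_identical(p$retention_weeks, 2)  # floor(20 / 7)
})

test_that("level achieved is the maximum completed level", {
  ev <- rbind(
    fix_events("u1", 0, "launch", 2),
    fix_events("u1", 10, "level_completed", 2, level = 2),
    fix_events("u1", 20, "level_completed", 2, level = 5)
  )
  p <- profile_user(build_timeline(fix_stream(ev), "u1"))
  expect_identical(p$level_achieved, 5L)
})

test_that("visit-count bands partition users into the four categories", {
  expect_identical(as.character(categorize(c(1, 2, 3, 4, 7, 8, 506))),
                   c("exploratory", "limited", "limited", "moderate",
                     "moderate", "committed", "committed"))
  expect_error(categorize(0), ">= 1")
  # total partition of 1..600
  expect_false(anyNA(categorize(1:600)))
})

test_that("two-stage mean weights users equally, not values", {
  expect_identical(two_stage_mean(list(A = c(2, 4), B = 6)), 4.5)
  expect_identical(two_stage_mean(list(A = c(10, 20))), 15)
  # all users single-valued: reduces to the ordinary mean
  expect_identical(two_stage_mean(list(1, 2, 9)), 4)
  expect_identical(
    two_stage_mean(data.frame(install_id = c("a", "a", "b"), value = c(2, 4, 6))),
    4.5)
  expect_error(two_stage_mean(list()), "at least one")
})

test_that("vectorized profiles equal per-user profiles on a synthetic stream", {
  pop <- generate_population(population_config(n_users = 25), seed = 3)
  sess <- sessionize_stream(pop$stream)
  profs <- compute_profiles(sess)
  for (id in sample(profs$install_id, 5)) {
    single <- profile_user(build_timeline(pop$stream, id))
    row <- profs[profs$install_id == id, ]
    rownames(row) <- rownames(single) <- NULL
    expect_equal(row, single, tolerance = 1e-12)
  }
})

test_that("descriptive table: group sizes sum to the all row; SD 0 for identical users", {
  pop <- generate_population(population_config(n_users = 300), seed = 21)
  profs <- compute_profiles(sessionize_stream(pop$stream))
  d <- descriptive_table(profs)
  all_n <- d$counts$n[d$counts$group == "all"]
  expect_identical(sum(d$counts$n[d$counts$group != "all"]), all_n)
  expect_identical(all_n, 300L)

  # hand-built five-user fixture: means verified by hand
  profs5 <- data.frame(
    install_id = paste0("u", 1:5), platform = c("android", "android", "ios", "ios", "ios"),
    license_accepted = c(TRUE, TRUE, TRUE, FALSE, TRUE),
    n_visits = c(1L, 1L, 2L, 4L, 9L), n_events = c(10L, 20L, 30L, 40L, 100L),
    active_minutes = c(1, 3, 10, 20, 50), retention_weeks = c(0, 0, 1, 4, 12),
    level_achieved = c(1L, 1L, 1L, 2L, 7L), mean_visit_minutes = c(1, 3, 5, 5, 50 / 9),
    first_use_ms = rep(T0, 5), last_use_ms = rep(T0, 5),
    category = c("exploratory", "exploratory", "limited", "moderate", "committed"),
    stringsAsFactors = FALSE
  )
  d5 <- descriptive_table(profs5)
  s <- d5$stats
  expect_identical(s$mean[s$group == "all" & s$metric == "active_minutes"], 16.8)
  expect_identical(s$mean[s$group == "1 visit" & s$metric == "n_events"], 15)
  expect_identical(s$sd[s$group == "1 visit" & s$metric == "active_minutes"],
                   sd(c(1, 3)))
  # a single-user group has SD NA; identical values give SD 0
  profs2 <- profs5[c(1, 1), ]; profs2$install_id <- c("a", "b")
  d2 <- descriptive_table(profs2)
  expect_identical(unique(d2$stats$sd[d2$stats$group == "1 visit"]), 0)
  expect_identical(d5$counts$license_pct[d5$counts$group == "all"], 80)
})

test_that("percentile table uses nearest-rank percentiles", {
  profs <- data.frame(
    install_id = sprintf("u%03d", 1:100), platform = "android",
    license_accepted = TRUE, n_visits = 1:100, n_events = 1L,
    active_minutes = 1, retention_weeks = 0, level_achieved = 1L,
    mean_visit_minutes = 1, first_use_ms = T0, last_use_ms = T0,
    category = as.character(categorize(1:100)), stringsAsFactors = FALSE
  )
  t2 <- percentile_table(profs)
  v <- t2[t2$group == "all" & t2$metric == "n_visits", ]
  expect_identical(v$value, c(25, 50, 75, 90))
  # all single-visit users: visit percentiles all 1
  v1 <- t2[t2$group == "1 visit" & t2$metric == "n_visits", ]
  expect_true(all(v1$value == 1L))
  # a single profile: every percentile equals its value
  tp <- percentile_table(profs[50, ])
  expect_true(all(tp$value[tp$metric == "n_visits"] == 50L))
})

test_that("printed-percentage arithmetic rounds half-up to two decimals", {
  expect_identical(proportion_pct(65458, 104067), 62.90)
  expect_identical(proportion_pct(0, 5), 0)
  expect_identical(proportion_pct(30948, 104067), 29.74)
  expect_identical(proportion_pct(1, 800), 0.13)  # 0.125 rounds up
  expect_error(proportion_pct(1, 0), "positive")
  expect_error(proportion_pct(5, 4), "numerator")
})

test_that("return use counts activity strictly after each window", {
  profs <- data.frame(
    install_id = c("a", "b", "c", "d"),
    first_use_ms = rep(T0, 4),
    last_use_ms = T0 + c(0, 2, 10, 40) * 86400000
  )
  profs <- cbind(profs, platform = "android", license_accepted = TRUE,
                 n_visits = c(1L, 2L, 3L, 4L), n_events = 1L, active_minutes = 1,
                 retention_weeks = 0, level_achieved = 1L, mean_visit_minutes = 1,
                 category = "exploratory")
  ru <- suppressWarnings(return_use(
    profs, windows_days = c("first day" = 1, "1 week" = 7, "1 month" = 30)))
  expect_identical(ru$numerator, c(3L, 2L, 1L))
  expect_identical(ru$denominator, rep(4L, 3))
  expect_identical(ru$pct, proportion_pct(ru$numerator, ru$denominator))
  # single-visit user is in no numerator
  expect_identical(ru$numerator[1], sum(profs$last_use_ms > profs$first_use_ms + 86400000))
  # proportions non-increasing
  expect_true(all(diff(ru$pct) <= 0))
})

test_that("windows longer than the observation span are flagged censored", {
  profs <- data.frame(install_id = "a", first_use_ms = T0,
                      last_use_ms = T0 + 86400000)
  expect_warning(
    ru <- return_use(profs, windows_days = c(short = 1, long = 365),
                     window_start_ms = T0, window_end_ms = T0 + 30 * 86400000),
    "censored")
  expect_identical(ru$censored, c(FALSE, TRUE))
})

test_that("the retention linter flags count/percent mismatch and monotonicity breaks", {
  clean <- data.frame(
    window = c("first day", "1 week"), numerator = c(30, 20),
    denominator = c(100, 100), pct = c(30, 20)
  )
  expect_identical(nrow(lint_retention(clean)), 0L)

  bad <- data.frame(window = "3 months", numerator = 10108,
                    denominator = 104067, pct = 17.40)
  flags <- lint_retention(bad)
  expect_identical(flags$check, "count_percent_mismatch")
  expect_match(flags$detail, "9.71")

  nonmono <- data.frame(window = c("1 month", "3 months"),
                        numerator = c(10, 20), denominator = c(100, 100),
                        pct = c(10, 20))
  expect_true("monotonicity" %in% lint_retention(nonmono)$check)
})

test_that("rolling retention counts distinct day, week and month blocks", {
  # all events in one day
  tl <- build_timeline(fix_stream(fix_events("u1", c(0, 100, 7200))), "u1")
  expect_identical(rolling_retention(tl), c(days = 1L, weeks = 1L, months = 1L))
  # first use Jan 1, next use Jan 8: day blocks 0 and 7, week blocks 0
  # and 1, month block 0 only
  jan1 <- as.numeric(as.POSIXct("2019-01-01 12:00:00", tz = "UTC")) -
    as.numeric(as.POSIXct("2018-08-01", tz = "UTC"))
  ev <- fix_events("u1", c(jan1, jan1 + 7 * 86400))
  r <- rolling_retention(build_timeline(fix_stream(ev), "u1"))
  expect_identical(r, c(days = 2L, weeks = 2L, months = 1L))
  # zero-duration records are not active use
  ev0 <- fix_events("u1", c(0, 86400 * 3), duration_s = c(5, 0))
  r0 <- rolling_retention(build_timeline(fix_stream(ev0), "u1"))
  expect_identical(r0, c(days = 1L, weeks = 1L, months = 1L))
})

test_that("rolling retention invariants hold population-wide", {
  pop <- generate_population(population_config(n_users = 120), seed = 14)
  sess <- sessionize_stream(pop$stream)
  roll <- rolling_retention(sess)
  profs <- compute_profiles(sess)
  expect_true(all(roll$active_days >= roll$active_weeks))
  expect_true(all(roll$active_weeks >= roll$active_months))
  single <- profs$install_id[profs$n_visits == 1L]
  expect_true(all(profs$retention_weeks[profs$n_visits == 1L] == 0))
  # single-visit users are active on one day (two only if the visit
  # straddles midnight)
  r1 <- roll[roll$install_id %in% single, ]
  expect_true(all(r1$active_days %in% c(1L, 2L)))
  expect_gte(mean(r1$active_days == 1L), 0.95)
})
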