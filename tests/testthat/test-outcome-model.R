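# Occasion-level table assembly and the polynomial repeated-measures model.

# Build a long table directly (bypassing event logs) for model-level tests.
sim_long <- function(n_users, occasions = 2, beta = c(50, 1), degree = 1,
                     tau = 4, sigma = 4, x_fun = function(k) runif(k, 0, 30)) {
  id <- rep(sprintf("s%04d", seq_len(n_users)), each = occasions)
  x <- x_fun(n_users * occasions)
  mu <- drop(outer(x, seq_along(beta) - 1L, `^`) %*% beta)
  u <- rep(rnorm(n_users, 0, tau), each = occasions)
  y <- mu + u + rnorm(length(x), 0, sigma)
  data.frame(install_id = id, total = y, observing = y / 5,
             acting_with_awareness = y / 5, nonjudging = y / 5,
             nonreactivity = y / 5, weeks_since_install = x,
             active_minutes = x, n_visits = pmax(1, round(x)),
             n_events = pmax(1, round(3 * x)), level_achieved = 1L,
             log_active_minutes = log1p(x), stringsAsFactors = FALSE)
}

test_that("assemble_long_table joins occasions to profiles and flags orphans", {
  scores <- data.frame(
    install_id = rep(c("a", "b", "c"), each = 2), occasion = rep(1:2, 3),
    timestamp_ms = T0 + rep(c(0, 10), 3) * 86400000,
    weeks_since_install = rep(c(0, 10 / 7), 3), level_at_assessment = 1L,
    observing = 12, acting_with_awareness = 15, nonjudging = 15,
    nonreactivity = 15, total = 57, stringsAsFactors = FALSE
  )
  profiles <- data.frame(
    install_id = c("a", "b", "c", "d"), platform = "android",
    license_accepted = TRUE, n_visits = c(2L, 3L, 4L, 1L),
    n_events = c(10L, 20L, 30L, 5L), active_minutes = c(5, 10, 20, 1),
    retention_weeks = 1, level_achieved = 1L, mean_visit_minutes = 2,
    first_use_ms = T0, last_use_ms = T0 + 10 * 86400000,
    category = "limited", stringsAsFactors = FALSE
  )
  expect_message(tab <- assemble_long_table(scores, profiles), "1 profiled")
  expect_identical(nrow(tab), 6L)
  expect_identical(tab$active_minutes, rep(c(5, 10, 20), each = 2))
  expect_identical(tab$log_active_minutes, log1p(tab$active_minutes))
  expect_identical(attr(tab, "n_users_unscored"), 1L)

  orphan <- scores; orphan$install_id[1:2] <- "ghost"
  expect_error(assemble_long_table(orphan, profiles), "ghost")
})

test_that("cumulative mode accrues engagement up to each occasion", {
  key <- ffmq_key()
  r <- stats::setNames(rep(3L, 19), key$items)
  mk_run <- function(at0) rbind(
    fix_events("u1", at0 + seq_len(19) * 5, "assessment_item", 3,
               item = key$items, response = r),
    fix_events("u1", at0 + 99, "assessment_completed", 1))
  ev <- rbind(
    fix_events("u1", 0, "launch", 60),       # 1 min
    fix_events("u1", 30, "other", 120),      # 2 min
    mk_run(200),
    fix_events("u1", 7200, "launch", 300),   # 5 min, second visit
    mk_run(7600)
  )
  sess <- sessionize_stream(fix_stream(ev))
  sc <- extract_assessments(sess, key)
  profs <- compute_profiles(sess)
  tab <- assemble_long_table(sc, profs, mode = "cumulative", sess = sess)
  # occasion 1: launch + other + 19 items of 3s + done of 1s
  expect_equal(tab$active_minutes[1], (60 + 120 + 19 * 3 + 1) / 60)
  expect_equal(tab$n_visits, c(1, 2))
  # totals mode: both occasions carry the end-of-study totals
  tab2 <- assemble_long_table(sc, profs, mode = "totals")
  expect_equal(unique(tab2$active_minutes), profs$active_minutes)
})

test_that("noiseless polynomial data is recovered exactly", {
  set.seed(1)
  beta <- c(40, 2, -0.5, 0.02)
  tab <- sim_long(80, occasions = 1, beta = beta, tau = 0, sigma = 0)
  suppressWarnings(fit <- fit_polynomial(tab, "total", "weeks_since_install",
                                         degree = 3))
  expect_false(fit$mixed)  # single-occasion users: single-level fallback
  expect_equal(unname(coef(fit)), beta, tolerance = 1e-6)
  expect_equal(r_squared(fit), 1, tolerance = 1e-9)
})

test_that("pure-noise outcomes give near-zero R-squared at large n", {
  set.seed(2)
  tab <- sim_long(600, occasions = 2, beta = c(50, 0), tau = 5, sigma = 5)
  fit <- fit_polynomial(tab, "total", "weeks_since_install", degree = 1)
  expect_true(fit$mixed)
  expect_lt(r_squared(fit), 0.01)
  expect_gt(fit$p_values[2], 0.001)  # slope indistinguishable from zero
})

test_that("slope estimates recover the generating value within Wald error", {
  set.seed(3)
  tab <- sim_long(400, occasions = 2, beta = c(50, 0.8), tau = 4, sigma = 4)
  fit <- fit_polynomial(tab, "total", "weeks_since_install", degree = 1)
  b1 <- coef(fit)[2]; se1 <- fit$se[2]
  expect_lt(abs(b1 - 0.8), 4 * se1)
  expect_lt(fit$p_values[2], 1e-6)
})

test_that("orthogonal and raw-power parameterizations give identical predictions", {
  set.seed(4)
  tab <- sim_long(100, occasions = 2, beta = c(30, 1, 0.1), tau = 3, sigma = 3)
  fit <- fit_polynomial(tab, "total", "weeks_since_install", degree = 2)
  raw_pred <- predict(fit, tab$weeks_since_install[stats::complete.cases(tab)])
  expect_equal(raw_pred, fit$fixed_pred, tolerance = 1e-8)
})

test_that("R-squared is invariant under affine predictor rescaling", {
  set.seed(5)
  tab <- sim_long(150, occasions = 2, beta = c(50, 0.6), tau = 3, sigma = 3)
  f1 <- fit_polynomial(tab, "total", "active_minutes", degree = 1)
  tab2 <- tab; tab2$active_minutes <- 3 * tab$active_minutes + 7
  f2 <- fit_polynomial(tab2, "total", "active_minutes", degree = 1)
  expect_equal(r_squared(f1), r_squared(f2), tolerance = 1e-8)
})

test_that("r_squared definitions behave at the extremes", {
  set.seed(6)
  tab <- sim_long(50, occasions = 1, beta = c(10, 2), tau = 0, sigma = 0)
  suppressWarnings(fit <- fit_polynomial(tab, "total", "weeks_since_install",
                                         degree = 1))
  expect_equal(r_squared(fit, "corr"), 1, tolerance = 1e-9)
  expect_equal(r_squared(fit, "variance"), 1, tolerance = 1e-6)
  # no true slope: both definitions near zero at moderate n
  tab0 <- sim_long(400, occasions = 1, beta = c(10, 0), tau = 0, sigma = 1)
  suppressWarnings(f0 <- fit_polynomial(tab0, "total", "weeks_since_install",
                                        degree = 1))
  expect_lt(r_squared(f0, "variance"), 0.02)
  expect_lt(r_squared(f0, "corr"), 0.02)
})

test_that("degenerate inputs fail informatively", {
  tab <- sim_long(30, occasions = 2)
  few <- tab; few$weeks_since_install <- rep(c(1, 2, 3), length.out = nrow(few))
  expect_error(fit_polynomial(few, "total", "weeks_since_install", degree = 2),
               "distinct predictor values")
  const <- tab; const$total <- 5
  expect_error(fit_polynomial(const, "total", "weeks_since_install", 1),
               "zero variance")
  expect_error(fit_polynomial(tab, "total", "weeks_since_install", degree = 4),
               "degree")
})

test_that("the model battery runs the full grid and reports per-cell results", {
  cfg <- population_config(n_users = 500, p_spontaneous = 0.15)
  pop <- generate_population(cfg, seed = 9)
  sess <- sessionize_stream(pop$stream)
  profs <- compute_profiles(sess)
  sc <- extract_assessments(sess)
  tab <- suppressMessages(assemble_long_table(sc, profs))
  bat <- fit_battery(tab)
  # 5 time models (cubic) + 4 engagement models (linear)
  expect_length(bat$fits, 9L)
  expect_true(all(is.na(bat$results$error)))
  # one row per term: cubic rows have 4 terms, linear rows 2
  expect_identical(nrow(bat$results), 5L * 4L + 4L * 2L)
  r2 <- bat$results$r_squared
  expect_true(all(r2 >= 0 & r2 <= 1, na.rm = TRUE))
  expect_true(all(bat$results$n_occasions >= bat$results$n_users, na.rm = TRUE))
})

test_that("battery failures are captured per cell, not propagated", {
  tab <- sim_long(40, occasions = 2)
  tab$level_achieved <- 1L  # constant predictor: that cell must fail
  bat <- fit_battery(tab)
  lvl <- bat$results[bat$results$predictor == "level_achieved", ]
  expect_false(is.na(lvl$error[1]))
  ok <- bat$results[bat$results$predictor == "active_minutes", ]
  expect_true(all(is.na(ok$error)))
})
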