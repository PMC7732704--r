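# Synthetic generator: determinism, validity, category structure, and
# agreement between intended and recovered quantities.

test_that("config validation enumerates bad fields", {
  expect_error(population_config(category_mix = c(0.5, 0.5, 0.2, 0.1)),
               "sum to 1")
  expect_error(population_config(p_license = 1.2), "p_license")
  expect_error(population_config(outcome = list(predictor = "shoe_size",
                                                beta = 1, tau = 1, sigma = 1)),
               "predictor unknown")
  expect_error(population_config(n_users = -1), "nonnegative")
})

test_that("n = 0 yields an empty but valid stream", {
  pop <- generate_population(population_config(n_users = 0), seed = 1)
  expect_identical(nrow(pop$stream$records), 0L)
  expect_s3_class(pop$stream, "event_stream")
})

test_that("the same seed reproduces the log byte for byte", {
  cfg <- population_config(n_users = 50)
  a <- generate_population(cfg, seed = 123)
  b <- generate_population(cfg, seed = 123)
  expect_identical(a$stream$records, b$stream$records)
  expect_identical(a$truth$users, b$truth$users)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_event_log(a$stream, f1); write_event_log(b$stream, f2)
  expect_identical(readLines(f1), readLines(f2))
  c_ <- generate_population(cfg, seed = 124)
  expect_false(identical(a$stream$records, c_$stream$records))
})

test_that("generated streams pass event-model validation record by record", {
  pop <- generate_population(population_config(n_users = 40), seed = 6)
  r <- pop$stream$records
  for (i in sample(nrow(r), 50, replace = TRUE)) {
    raw <- list(install_id = r$install_id[i], timestamp_ms = r$timestamp_ms[i],
                event_name = r$event_name[i], duration_s = r$duration_s[i])
    if (!is.na(r$content_area[i])) raw$content_area <- r$content_area[i]
    pl <- list()
    if (!is.na(r$level[i])) pl$level <- r$level[i]
    if (!is.na(r$item[i])) { pl$item <- r$item[i]; pl$response <- r$response[i] }
    if (!is.na(r$platform[i])) pl$platform <- r$platform[i]
    if (length(pl)) raw$payload <- pl
    expect_s3_class(validate_record(raw), "event_record")
  }
})

test_that("sessionization recovers the generator's intended visit counts", {
  pop <- generate_population(population_config(n_users = 150), seed = 44)
  profs <- compute_profiles(sessionize_stream(pop$stream))
  truth <- pop$truth$users
  m <- match(profs$install_id, truth$install_id)
  expect_identical(profs$n_visits, truth$n_visits[m])
  expect_identical(as.character(profs$category), truth$category[m])
  # realized engagement in the truth equals the pipeline's measurement
  expect_equal(profs$active_minutes, truth$active_minutes[m], tolerance = 1e-9)
  expect_identical(profs$level_achieved, truth$level_achieved[m])
})

test_that("per-category construction: visits, license, platform", {
  set.seed(10)
  ex <- generate_user("exploratory")
  expect_identical(max(sessionize_stream(ex$stream)$visits$visit_index), 1L)
  com <- generate_user("committed")
  expect_gte(max(sessionize_stream(com$stream)$visits$visit_index), 8L)

  # a non-accepting population still launches the app
  cfg <- population_config(n_users = 30, p_license = 0)
  pop <- generate_population(cfg, seed = 2)
  expect_false(any(pop$stream$records$event_name == "eula_accepted"))
  expect_true(any(pop$stream$records$event_name == "launch"))
})

test_that("category mix converges to the configured proportions", {
  cfg <- population_config(n_users = 10000)
  pop <- generate_population(cfg, seed = 7)
  profs <- compute_profiles(sessionize_stream(pop$stream))
  got <- prop.table(table(factor(profs$category, levels = names(cfg$category_mix))))
  expect_true(all(abs(got - cfg$category_mix) < 0.02))
})

test_that("assessment prompting follows the level schedule and compliance", {
  # full compliance, no abandonment, no spontaneous assessments: a user
  # reaching level 7 has exactly the two prompted occasions
  cfg <- population_config(p_comply = c(1, 1, 1), p_spontaneous = 0,
                           p_abandon = 0)
  set.seed(15)
  occ <- generate_ffmq_occasions(10, new_level = c(NA, 2L, 3L, NA, 4L, 5L, 6L,
                                                   7L, NA, NA), config = cfg)
  expect_identical(occ$trigger, c("prompt_level1", "prompt_level7"))
  expect_identical(occ$visit_index, c(1L, 8L))
  # zero compliance: no occasions at all
  cfg0 <- population_config(p_comply = c(0, 0, 0), p_spontaneous = 0)
  occ0 <- generate_ffmq_occasions(10, new_level = c(NA, 2L, 3L, NA, 4L, 5L, 6L,
                                                    7L, NA, NA), config = cfg0)
  expect_identical(nrow(occ0), 0L)
  # unlicensed users are never assessed
  occ_u <- generate_ffmq_occasions(5, config = cfg, licensed = FALSE)
  expect_identical(nrow(occ_u), 0L)
})

test_that("noiseless positive slope makes totals increase with engagement", {
  cfg <- population_config(
    n_users = 250,
    outcome = list(predictor = "log_active_minutes", beta = c(30, 6),
                   tau = 0, sigma = 0),
    p_comply = c(1, 0, 0), p_spontaneous = 0, p_abandon = 0)
  pop <- generate_population(cfg, seed = 33)
  occ <- pop$truth$occasions
  expect_gt(nrow(occ), 50)
  m <- match(occ$install_id, pop$truth$users$install_id)
  eng <- log1p(pop$truth$users$active_minutes[m])
  # realized totals are the rounded/clamped latent: monotone up to rounding
  expect_gt(stats::cor(eng, occ$realized_total), 0.99)
  o <- order(eng)
  expect_true(all(diff(occ$realized_total[o]) >= -1))
})

test_that("scored occasions reproduce the generator's realized totals exactly", {
  cfg <- population_config(n_users = 200, p_abandon = 0.2, p_spontaneous = 0.1)
  pop <- generate_population(cfg, seed = 21)
  sess <- sessionize_stream(pop$stream)
  sc <- extract_assessments(sess)
  occ <- pop$truth$occasions
  expect_identical(nrow(sc), nrow(occ))
  m <- match(paste(sc$install_id, sc$timestamp_ms),
             paste(occ$install_id, occ$timestamp_ms))
  expect_false(anyNA(m))
  expect_equal(sc$total, occ$realized_total[m])
  expect_identical(attr(sc, "n_abandoned"), pop$truth$n_abandoned)
  # subscale identities: totals are the sum of the four subscales, in bounds
  expect_equal(sc$total, sc$observing + sc$acting_with_awareness +
                 sc$nonjudging + sc$nonreactivity)
  expect_true(all(sc$total >= 19 & sc$total <= 95))
})

test_that("heavy right-skew: mean visits well above the median", {
  pop <- generate_population(population_config(n_users = 3000), seed = 18)
  profs <- compute_profiles(sessionize_stream(pop$stream))
  expect_gt(mean(profs$n_visits), stats::median(profs$n_visits))
  expect_gt(max(profs$n_visits), 30)
  expect_lte(max(profs$n_visits), 506)
  # license acceptance close to the configured 87.8%
  expect_lt(abs(mean(profs$license_accepted) - 0.878), 0.03)
  # platform split close to 62.9% android
  expect_lt(abs(mean(profs$platform == "android") - 0.629), 0.03)
})
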