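# mhengage

Engagement analytics for anonymized mobile mental-health (mHealth) app
telemetry.

Free self-help apps reach hundreds of thousands of downloads, but almost
everything interesting about them — who keeps using them, for how long,
which screens they touch, and whether use relates to the outcome the app
targets — has to be reconstructed from raw event logs.  `mhengage`
implements that reconstruction end to end for a mindfulness-training app
whose telemetry consists of timestamped JSON-lines records (installation
id, event name, content-area label, duration) including in-app
administrations of the Five-Facet Mindfulness Questionnaire short form
(FFMQ-SF, 19 items over 4 subscales).  It is aimed at digital-health
researchers analysing natural-use ("in the wild") cohorts.

## What it computes

* **Sessionization.** Events are records with nonzero duration; durations
  are capped at 30 min unless the user raised the cap; a *visit* is a
  maximal cluster of records less than 30 min apart; visits are typed
  first-time (contains the EULA acceptance) or return.
* **Engagement profiles.** Per installation: visits, events, active
  minutes, whole-week retention, highest level achieved (1–14), and the
  four-category taxonomy — exploratory (1 visit), limited (2–3), moderate
  (4–7), committed (8+).
* **Retention.** Return-use proportions per window (1 day … 12 months,
  censoring-aware) with an internal-consistency linter, and rolling
  retention (distinct active days / weeks / months per user).
* **Navigation.** First content area, area entries, and distinct-area
  counts per session type, with Pearson chi-square between-group tests.
* **FFMQ-SF scoring.** Occasion extraction (completed vs abandoned runs),
  reverse scoring, subscale and total scores in [19, 95], loadable YAML
  key.
* **Dose–response models.** Polynomial repeated-measures regression of
  FFMQ-SF on one engagement predictor at a time:

  y_ij = β₀ + β₁P₁(x_ij) + … + β_dP_d(x_ij) + u_i + ε_ij,
  u_i ~ N(0, τ²), ε_ij ~ N(0, σ²)

  fitted by REML with a per-installation random intercept (lme4),
  orthogonal basis internally, coefficients reported on the raw scale,
  marginal pseudo-R².
* **Synthetic telemetry.** A seeded generator producing event logs with
  the structure above plus ground truth, so every stage is testable and
  the estimator is validated by parameter recovery.

## Worked example

```r
library(mhengage)

pop  <- generate_population(population_config(n_users = 1000), seed = 42)
pop$stream
#> <event_stream> 69333 records, 1000 installations
#>   window: 2018-08-01 .. 2019-04-08 (UTC)

sess  <- sessionize_stream(pop$stream)
profs <- compute_profiles(sess)
table(profs$category)
#>   committed exploratory     limited    moderate
#>         118         405         307         170

proportion_pct(sum(profs$license_accepted), nrow(profs))
#> [1] 87.8

return_use(profs, window_start_ms = pop$stream$window_start_ms,
           window_end_ms = pop$stream$window_end_ms)[1:3, c(1, 3:5)]
#>      window numerator denominator  pct
#> 1 first day       538        1000 53.8
#> 2    1 week       341        1000 34.1
#> 3   1 month       127        1000 12.7

sc  <- extract_assessments(sess)
tab <- assemble_long_table(sc, profs)
fit <- fit_polynomial(tab, "total", "log_active_minutes", degree = 1)
summary(fit)
#> Polynomial repeated-measures fit: total ~ poly(log_active_minutes, 1)
#> 397 occasions, 329 users; random intercept per installation
#>             estimate       se       z   p_value
#> (Intercept) 50.70810  1.32696 38.2138 < 2.2e-16 ***
#> x^1          2.13756  0.46032  4.6436 3.423e-06 ***
#> Random-intercept variance 45.430, residual variance 34.956
#> R^2 (corr) = 0.051
```

Read it as: 1,000 simulated installations produced 69,333 telemetry
records; 40.5% opened the app exactly once and 11.8% came back eight or
more times; 53.8% used the app again after the first day.  Among the 329
users who completed at least one in-app FFMQ-SF, each log-unit of active
minutes is associated with 2.14 additional points of total score
(true generating slope: 2.5, within the Wald interval), with most residual
variation between users (τ² = 45.4) rather than between occasions.

The one-call pipeline writes all artifacts (visits, profiles, descriptive
and percentile tables, retention, navigation, FFMQ scores, model battery,
and a Markdown report whose every percentage is recomputed from the counts
beside it):

```r
run_pipeline(run_config(simulate = population_config(n_users = 1000),
                        out_dir = "out", seed = 42))
```

A thin command-line wrapper lives at `inst/scripts/mhe.R`
(`run`, `simulate`, `validate`, `sessionize` subcommands).

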