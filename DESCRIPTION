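Package: mhengage
Title: Engagement Analytics for Mobile Mental-Health App Telemetry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing anonymized mobile-app event logs from
    mental-health (mHealth) interventions: reading and validating JSON-lines
    telemetry, sessionizing event streams into visits with an inactivity-gap
    rule, per-installation engagement profiles and user-category taxonomies,
    return-use and rolling-retention reports, click-stream content-area
    navigation tables, scoring of the in-app Five-Facet Mindfulness
    Questionnaire Short Form (FFMQ-SF, 19 items over 4 subscales), and
    polynomial repeated-measures mixed models relating engagement to
    questionnaire outcomes. Includes a seeded synthetic event-log generator
    with known ground truth so every pipeline stage can be validated by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    graphics,
    grDevices,
    jsonlite,
    lme4,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
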