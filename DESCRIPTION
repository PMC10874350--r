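Package: lonelykeys
Title: Diurnal Smartphone Keystroke Profiles and Loneliness
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline linking loneliness level, measured with the
    8-item UCLA Loneliness Scale (ULS-8), to diurnal smartphone keystroke
    patterns. Ingests per-participant keystroke event logs, applies a
    weekly-completeness filter, builds five-bin diurnal typing-count and
    count-ratio profiles (overall and split by weekday/weekend), extracts
    quadratic shape coefficients and weekday-weekend cosine similarity, and
    runs the group-level statistical battery (one-way ANOVA, Tukey-Kramer
    post-hoc, Welch's t-test). Includes an inhomogeneous-Poisson synthetic
    cohort generator so the whole analysis is testable without real data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
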