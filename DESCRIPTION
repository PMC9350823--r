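Package: dosefreq
Title: Dose-Response Analysis of Self-Managed Digital Speech-Language Therapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for studying dosage-frequency effects in
    self-managed digital speech-language and cognitive therapy. Provides a
    session-level domain-score algorithm based on task progression orders, a
    cohort-preparation layer that applies activity-based inclusion rules and
    bins patients into days-per-week dosage groups, a linear mixed-effects
    inference layer with slope contrasts, estimated marginal means,
    Tukey-adjusted pairwise comparisons and standardized pre/post effect
    sizes, and a synthetic-cohort simulator with adaptive task-difficulty
    progression for validating every stage without access to proprietary
    app data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    lme4,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    emmeans,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
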