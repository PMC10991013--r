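Package: vienna
Title: Psychometric Evaluation of the VIENNA Spatial Navigation Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scoring and psychometric evaluation tools for the VIENNA
    virtual-environments spatial navigation assessment. Implements the
    three-class scoring rubric with spatial-updating and perspective-rotation
    error typing, item difficulty relative to chance expectation, Wilson's e
    corrected item-total correlation, polychoric correlations and ordinal
    alpha, distribution-shape diagnostics with the 3.29 z rule, medcouple
    adjusted-boxplot outlier detection, a correlation and partial-correlation
    battery with Benjamini-Hochberg correction, forced-entry regression with
    p-based backward reduction and an AIC cross-check, and a seeded
    latent-trait cohort simulator for end-to-end testing without raw
    participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    car,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
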