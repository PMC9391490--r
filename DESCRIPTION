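Package: toothchron
Title: Dental Chronology from von Ebner Increments in Polyphyodont Amniotes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers tooth age, tooth longevity, and tooth replacement rate
    from incremental lines of von Ebner measured on histological thin
    sections of polyphyodont amniote dentitions. Provides transect-level
    increment statistics with gap extrapolation and oblique-sectioning
    correction, direct and resorption-pit-based replacement-rate
    estimators with explicit minimum-rate handling, diet-group summaries,
    a permutation test for the body-mass association, Brownian-motion
    ancestral state reconstruction on a time-calibrated phylogeny, and a
    seeded synthetic dentine-growth simulator for validating every
    estimator by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    phytools,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
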