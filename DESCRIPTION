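Package: speedchange
Title: Speed-Change Discrimination for Motion in Depth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for designing, simulating and analysing two-interval
    forced-choice (2IFC) speed-change discrimination experiments for motion
    in depth. Implements the perspective kinematics that map constant world
    speed onto accelerating retinal speed, the distance- and
    duration-conserving speed-change stimulus ladders, seeded synthetic
    observers, constrained cumulative-normal psychometric fitting with 75%
    thresholds, 2x2 repeated-measures ANOVA with partial eta squared,
    between-subject confidence intervals, and JZS paired-contrast Bayes
    factors. A synthetic-cohort generator reproduces the trial-level
    structure of a 9-participant, 8-condition study so the full pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
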