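Package: sednet
Title: Physical Behavior, Brain Network Efficiency, and Decision-Making Competence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis pipeline linking accelerometer-measured
    sedentary time and moderate-to-vigorous physical activity to decision-making
    competence through the efficiency of resting-state functional brain networks.
    Provides minute-epoch accelerometer processing (non-wear detection,
    count-based intensity classification, valid-day rules), construction of
    weighted functional connectivity matrices from regional BOLD time series
    (Fisher z transformation, Bonferroni edge thresholding, rescaling to [0,1]
    weights), weighted global and local graph efficiency, scoring of the six-test
    adult decision-making competence battery, and a three-step mediation analysis
    with percentile bootstrap confidence intervals for the indirect effect.
    A seeded synthetic-cohort generator with planted exposure-mediator-outcome
    structure makes every stage testable without access to participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    tools,
    graphics
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
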