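Package: vis4m
Title: Alternation, Transition and Stimulus Analysis for the Visual-Stimuli Four-Arm Maze
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Scores spontaneous alternation and arm-transition statistics from
    arm-entry event logs recorded in a visual-stimuli four-arm maze, with
    analytic and Monte-Carlo chance-level null models, photometric and
    opsin-effective characterization of the arm stimuli (exposure-value,
    illuminance, luminance, irradiance and photon-flux conversions; visual
    pigment nomogram templates), cohort-level statistics (two-way ANOVA with
    Fisher's LSD post-hoc, transition-predictor regressions), Circos chord-table
    export, and a semi-Markov simulator of four-arm free exploration with
    likelihood-based parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    car,
    jsonlite,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    emmeans,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
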