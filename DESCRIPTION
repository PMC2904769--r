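Package: stridegem
Title: Goal Equivalent Manifold Analysis of Stride-to-Stride Variability
    in Treadmill Walking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for analysing how walkers regulate stride-to-stride
    fluctuations on a motorized treadmill. Decomposes stride time and
    stride length series into deviations tangent and perpendicular to the
    goal equivalent manifold (GEM) of constant-speed walking, quantifies
    their temporal structure with first-order detrended fluctuation
    analysis (DFA), tests alternative regulation hypotheses with
    constraint-respecting surrogate series (independent shuffle,
    phase-randomized, paired shuffle), and simulates stochastic
    single-step optimal controllers (minimum intervention, preferred
    operating point, and over-correcting variants) on the discrete
    stride-to-stride map. Includes a fractional Gaussian noise generator
    for DFA calibration and an end-to-end analysis pipeline with tidy
    summary tables.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
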