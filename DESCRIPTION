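Package: perchjump
Title: Keel-Force and Locomotion Analysis of Perch-to-Perch Transitions in
    Laying Hens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how perch positioning (direction, angle,
    distance) affects laying-hen locomotion and the forces experienced at
    the keel bone. Encodes the 2x2x2 factorial geometry of a
    platform-to-perch jump experiment with counterbalanced scheduling,
    simulates ground-truth study data including 800 Hz triaxial
    accelerometer traces, extracts per-jump peak forces, impulses,
    latencies and balancing outcomes from event-windowed traces, and fits
    hierarchical Gaussian and binomial mixed models with nested and
    crossed random intercepts, parametric-bootstrap likelihood-ratio model
    reduction, back-transformed effect estimates and simulated quantile
    residual diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    minqa,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
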