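Package: camtrapniche
Title: Occupancy, Co-Occurrence and Diel Activity Analysis for Camera-Trap Surveys
Version: 0.1.0
Authors@R: person("camtrapniche", "developers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing camera-trap surveys of small-carnivore
    communities. Builds detection histories from timestamped record tables,
    computes station-level vegetation covariates and diversity indices
    (Shannon H, Pielou J, Fisher alpha), fits single-season site-occupancy
    models with imperfect detection by maximum likelihood, ranks and averages
    models by AICc/QAICc with MacKenzie-Bailey parametric-bootstrap
    goodness-of-fit (c-hat), fits conditional two-species occupancy models
    (psiBa/rBa parameterization) and species interaction factors for occupancy
    (Phi) and detection (delta), and estimates circular diel activity
    densities with von Mises kernels, 50%/95% highest-density isopleths and
    overlap coefficients (OVL). A fully seeded synthetic-survey generator
    makes every stage testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
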