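Package: radonrisk
Title: Occupancy-Conditioned Indoor Radon Dose Estimation and Risk Classification
Version: 0.1.0
Authors@R: person("radonrisk", "maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Tools for continuous indoor radon risk assessment. Aggregates
    timestamped radon concentration series over occupancy schedules into
    windowed mean concentrations, indoor effective doses and annualized dose
    estimates, and classifies the result on a four-level colour-coded risk
    scale referenced to ICRP public and occupational dose limits. Includes
    a reference dose abacus over concentration and daily occupancy, a
    log-normal synthetic series generator for hermetic testing, and a small
    command-line front end with report writers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
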