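Package: cico
Title: Profile-Likelihood Confidence Intervals by Constrained Optimization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Practical identifiability analysis for models fitted by maximum
    likelihood. Instead of tracing the profile likelihood step by step, each
    confidence-interval endpoint is obtained directly as the solution of a
    constrained optimization problem: minimize (or maximize) a single parameter
    subject to the negative log-likelihood staying below a likelihood-ratio
    threshold, solved with an augmented Lagrangian around a derivative-free
    local optimizer. Scan bounds give a formal termination criterion for
    practically non-identifiable parameters. Includes a stepwise
    profile-likelihood baseline for validation, bundled toy objectives, a
    synthetic-data generator with a weighted sum-of-squares likelihood,
    plotting helpers and a small command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
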