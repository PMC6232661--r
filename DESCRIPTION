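Package: hfacsbn
Title: Bayesian Network Modelling of Needlestick and Sharps Injuries
    Under the HFACS Framework
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds, trains and interrogates a discrete Bayesian network for
    occupational needlestick and sharps injury (NSI) risk among hospital
    nurses, with the network structure fixed by the four-level Human Factors
    Analysis and Classification System (HFACS).  Provides questionnaire
    preprocessing (Likert scale scoring, Cronbach alpha reliability,
    straight-lining filters, discretization into ordered states),
    expectation-maximization parameter learning that tolerates missing
    answers, exact inference by variable elimination with a brute-force
    enumeration cross-check, model validation by proper scoring rules
    (error rate, logarithmic loss, quadratic loss, spherical payoff),
    mutual-information and predictive-reasoning sensitivity analysis,
    what-if intervention evaluation, and a calibrated synthetic
    questionnaire generator so the whole pipeline can be exercised end to
    end without access to confidential hospital data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
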