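Package: pahrank
Title: Ranking Long-Term Care Facilities by Potentially Avoidable Hospitalisations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying long-term care facilities whose residents have
    high use of acute hospital admissions. Classifies hospital discharge events as
    potentially avoidable hospitalisations (PAH) by matching any of the first three
    diagnosis codes against a configurable condition code list, computes
    person-time at risk exactly from dates or via a care-level mean-survival
    approximation, fits a negative-binomial mixed model with a facility random
    intercept by adaptive Gauss-Hermite quadrature with backward covariate
    elimination, and ranks facilities by four methods (events per resident, events
    per person-year, model-predicted counts, and change in ranks) plus a model
    residual variant. Includes a seeded synthetic cohort generator emulating
    residents nested in facilities with care-level-dependent survival and
    overdispersed event counts, and a file-based pipeline with a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
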