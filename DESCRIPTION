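Package: ltctraj
Title: Multimorbidity Trajectories from Longitudinal Condition Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing trajectories of multimorbidity (the
    accumulation and resolution of long-term conditions, LTCs) in
    longitudinal primary-care records. Builds five-state histories
    (0/1/2/3+ active conditions and death) from dated onset and
    resolution events, fits a covariate-adjusted continuous-time
    multistate Markov model by maximum likelihood (hazard ratios,
    one-year transition probability matrices, mean sojourn times),
    estimates mean cumulative function curves of condition acquisition
    with death as censoring, and mines first-order Markov chains of
    disease sequences with top-k antecedent/consequent selection. A
    configurable synthetic electronic-health-record cohort generator
    with known transition intensities supports parameter-recovery
    studies and end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    Matrix,
    deSolve,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
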