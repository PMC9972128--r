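Package: fccat
Title: Forced-Choice Computerized Adaptive Testing with the Thurstonian IRT Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An engine for multidimensional forced-choice (MFC) assessment with
    dominance items under the Thurstonian item response theory model. Implements
    the pairwise probit response function, per-pair Fisher information and
    Bayesian posterior information, maximum a posteriori (MAP) trait scoring,
    A-optimality pair selection under social-desirability balancing constraints,
    static-optimal test assembly targeted at the population origin, synthesis of
    calibrated item banks from summary statistics, and a simulation harness
    comparing adaptive and static designs under different desirability
    thresholds with SEM, correlation, and RMSE precision metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
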