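Package: healthvep
Title: Health Poverty Vulnerability Analysis for Survey Microdata
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for measuring multidimensional physical and mental
    health poverty in individual-level survey microdata and for modelling
    vulnerability as expected poverty (VEP).  Implements Alkire-Foster
    identification with configurable indicator systems and cutoffs,
    three-stage feasible generalized least squares estimation of a
    heteroskedastic welfare model with normal-CDF vulnerability
    prediction, income elasticity of health demand via log-log
    regression (global or stratified), a two-layer logistic regression
    with interaction terms, average marginal effects and joint Wald
    tests, coefficient-of-variation and Theil entropy inequality
    indices, and a calibrated synthetic microdata generator with known
    ground truth for end-to-end validation of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
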