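Package: welchslope
Title: Extended Welch Test, Power, and Sample Size for Comparing Two
    Regression Slopes
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tests the equality of the slopes of two simple linear
    regression lines when the group error variances may differ, using the
    extended Welch statistic with Satterthwaite-type approximate degrees
    of freedom.  Provides analytic power functions for design planning
    under the unconditional (random-predictor) framework -- a simplified
    noncentral-t approximation and a mixed-t approximation that averages
    over the chi-square distributions of the predictor sums of squares --
    together with minimal sample-size determination at a fixed allocation
    ratio and a Monte Carlo engine for empirical power and type-I-error
    assessment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    pracma,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
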