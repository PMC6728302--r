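Package: crgof
Title: Goodness-of-Fit Tests for the Compound Rayleigh Distribution
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for testing whether complete or type-II right-censored
    lifetime data follow the two-parameter Compound Rayleigh distribution.
    Provides the distribution functions, censored maximum-likelihood
    estimation by profile likelihood, modified Kolmogorov-Smirnov,
    Cramer-von Mises and Anderson-Darling statistics for censored samples,
    Monte Carlo critical-value tables, power simulation against standard
    lifetime alternatives, and end-to-end hypothesis tests with parametric
    bootstrap p-values.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
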