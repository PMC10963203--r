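Package: domcalib
Title: Calibration Estimators of Small-Domain Totals under Unit Non-Response
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Minimum chi-square (calibration) estimation of small-domain
    totals from surveys affected by unit non-response, with Hansen-Hurwitz
    subsampling of non-respondents.  Implements four weight systems -- ratio,
    generalized regression (GREG), exponential, and power -- in both
    single-phase sampling (domain auxiliary totals known) and two-phase
    double sampling (domain auxiliary totals estimated from a first-phase
    sample).  Includes a synthetic finite-population generator for
    positively skewed auxiliaries with per-domain non-response strata, and a
    design-based Monte Carlo engine that evaluates absolute relative bias
    and simulated relative standard error per estimator and domain.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
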