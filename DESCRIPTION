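Package: gsrecalc
Title: Three-Stage Group Sequential Designs with Sample Size Recalculation
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Design and evaluation of three-stage clinical trials with
    unblinded sample size recalculation at the first interim analysis.
    Implements inverse normal combination testing with Pocock-type efficacy
    boundaries computed by recursive numerical integration, closed-form
    conditional rejection probabilities and three-stage conditional power,
    three recalculation rules (observed conditional power, expected sample
    size optimization, and global score optimization), global and conditional
    performance scores, and a vectorized Monte Carlo engine for operating
    characteristics of two-arm trials with normally distributed endpoints.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    pracma,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
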