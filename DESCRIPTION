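Package: clusterbias
Title: Cluster Bias Testing in Two-Level Confirmatory Factor Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Maximum-likelihood estimation of balanced two-level one-factor
    measurement models and item-level tests for cluster bias (level-2
    measurement non-invariance). Implements both the free-baseline and the
    constrained-baseline 2-df unscaled likelihood-ratio testing strategies,
    a level-2 violator data simulator with intraclass-correlation control,
    and a Monte Carlo harness that tallies true-positive, false-positive,
    negative-likelihood-difference and non-convergence rates across a
    factorial design, with eta-squared ANOVA summaries of the results.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
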