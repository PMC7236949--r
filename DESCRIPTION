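Package: bnbpower
Title: Simulation-Based Power Analysis for Paired RNA-Seq Designs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Power and false-positive-rate estimation for RNA-Seq
    differential expression with paired or repeated measurements. Implements
    the bivariate negative binomial model for paired counts with
    likelihood-ratio and Wald tests on the fold ratio, Poisson and negative
    binomial generalized linear mixed models with a subject random intercept
    fitted by adaptive Gauss-Hermite quadrature, empirical-null (empirical
    parametric test) and asymptotic chi-square critical values, Monte Carlo
    power and false-positive-rate estimation over scenario grids,
    sample-size search for a target power, and per-gene fitting of pilot
    paired count matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    optparse,
    jsonlite,
    pracma,
    yaml
Suggests:
    lme4,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
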