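Package: circamix
Title: Mixed-Effects Cosinor Models for Longitudinal Circadian Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits single-component cosinor (sinusoidal regression) models to
    sparse, non-uniformly sampled longitudinal data within a linear
    mixed-effects framework. The nonlinear rhythm parameters (MESOR,
    amplitude, acrophase) are recovered from the linearized fit, estimated
    marginal means are computed over categorical covariate grids with
    optional conditioning, and confidence intervals and hypothesis tests
    for group differences in the nonlinear parameters are obtained by
    parametric or cluster bootstrap. Includes a synthetic-data generator
    for longitudinal circadian designs and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    emmeans,
    ggplot2,
    jsonlite
Config/testthat/edition: 3
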