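Package: demandtx
Title: Behavioral-Economic Demand Modeling with Transcriptomic Integration
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Exponential reinforcer-demand analysis for drug
    self-administration experiments and its integration with bulk gene
    expression. Fits the exponential demand equation to per-subject
    consumption data by nonlinear least squares (individually or with a
    shared range constant k across subjects or groups), derives essential
    value, Pmax and Omax, compares demand elasticity between groups with
    the extra sum-of-squares F test, and runs per-gene negative-binomial
    regressions of expression on individual essential value with
    Benjamini-Hochberg correction. Includes a synthetic cohort generator
    (demand curves on an escalating fixed-ratio price ladder plus
    negative-binomial expression matrices with a planted EV-linked gene
    fraction) and a reproducible end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    minpack.lm,
    withr
Config/testthat/edition: 3
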