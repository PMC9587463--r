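Package: nichebreadth
Title: Partitioning Thermal Niche Breadth Among Genotypes Within Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting how a population's thermal niche breadth is
    accrued from the genotypes (full-sibling families) it contains. Fits
    hierarchical zero-inflated thermal performance curves, based on a
    mode-normalised Kumaraswamy kernel, to family-structured growth-rate data
    by Bayesian sampling; derives family- and population-level thermal optima
    and 50%-performance breadths with credible intervals, among-family
    variance components, and envelope-style population breadths; and tests
    whether population breadth is predicted by family breadth, by genetic
    variation in thermal optimum, or by genetic variation in thermal breadth,
    using linear mixed-effects models with a species-pair random intercept.
    Includes a synthetic-data generator emulating paired-population
    growth-chamber experiments with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    lmerTest,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
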