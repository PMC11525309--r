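Package: mspe
Title: Model-Implied Simulation-Based Power Estimation for the z-Test
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation-based power analysis for single-parameter z-tests.
    Fits parametric power curves (probit regression on the square root of
    the sample size, and related probit/logit variants, plus a two-sided
    Wald variant and a naive linear-interpolation baseline) to logs of
    simulated significance decisions, computes confidence bands for the
    predicted power, and inverts the fitted curve for the required sample
    size with a confidence-band-calibrated lower bound. Includes a
    self-contained structural equation model (SEM) engine with normal-theory
    maximum likelihood and sandwich (robust) standard errors, an
    unconstrained product-indicator construction for latent interactions,
    synthetic data generators for a linear SEM and a quadratic/interaction
    SEM under multivariate normality or Vale-Maurelli non-normality, and a
    study runner that orchestrates power studies and evaluates power-curve
    models by bias, root mean squared error, and type I error of the
    sample-size lower bound.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
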