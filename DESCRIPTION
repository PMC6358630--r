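Package: prodsuit
Title: Bayesian Production-Environmental Suitability Modelling for
    Coastal Seaweed Harvests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fits a saturating (Michaelis-Menten form) production curve to
    annual seaweed harvest series driven by an additive environmental
    suitability index built from seven normalized environmental covariates
    (rainfall, seawater CO2, sea-surface temperature, typhoon counts, solar
    radiation, water nutrients, water quality) and a latent, positive
    human-disturbance state with a Gaussian random-walk smoothness prior.
    Estimation is by adaptive Metropolis-within-Gibbs MCMC with conjugate
    updates for the maximum-production and variance parameters. Includes
    factor-contribution percentages, a decline decomposition of multi-year
    production losses into suitability losses, piecewise linear-trend
    comparison of the disturbance trajectory, a seeded synthetic-data
    generator, and a CSV-based pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    rjags,
    coda
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
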