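Package: soilrisk
Title: Soil Heavy-Metal Pollution Indices, PMF Source Apportionment and
    Probabilistic Health Risk Assessment
Version: 0.1.0
Authors@R: person("soilrisk", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing heavy-metal concentrations in surface
    soils: summary statistics and exceedance screening against background
    and regulatory guide values, enrichment factors with Sutherland
    classification, Pearson correlation screening, a from-scratch
    uncertainty-weighted positive matrix factorization (PMF) receptor
    model for source apportionment, deterministic and Monte Carlo
    three-route (ingestion, dermal, inhalation) human health risk
    assessment (hazard index and total carcinogenic risk), inverse
    distance weighted interpolation of concentration surfaces, and a
    synthetic-data generator with known factor structure so the whole
    chain is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
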