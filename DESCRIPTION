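Package: fishcast
Title: Coupled Size-Spectrum and Bioeconomic Simulation of the Global Fishery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale, gridded simulator of the global wild-capture fishery.
    Fish communities are represented as body-mass size spectra driven by sea-surface
    temperature and net primary production, with temperature-dependent growth and
    mortality and density-dependent recruitment. Each grid cell is two-way coupled
    to an open-access economic model in which fishing effort responds to local
    profit, with technology (catchability), ex-vessel price and cost-per-unit-effort
    scenarios. Includes a synthetic Earth-like forcing generator, historical
    hindcast and future projection experiments, a transient catchability-ramp
    estimator of maximum sustainable yield, and rejection approximate Bayesian
    computation calibration that selects a maximally spread five-member parameter
    ensemble.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
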