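Package: fanherit
Title: Heritability and Evolvability of Paternal Fanning Behaviour from
    Pedigreed Common-Garden Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative-genetic analysis of paternal care behaviour in
    species where fathers are the sole caregivers, built around a father-son
    common-garden design. Provides pedigree parsing and the additive
    (numerator) relationship matrix by the tabular method, a Gibbs-sampled
    Bayesian univariate animal model with inverse-gamma variance priors,
    posterior summaries of heritability, repeatability and evolvability
    (CV_A, I_A), MCMC convergence diagnostics (lag autocorrelation and a
    Heidelberger-Welch stationarity test), a quadratic random-slope model of
    behaviour across the care period, an observation-window sampling-error
    robustness simulation, and a synthetic-data generator with known ground
    truth emulating the study design.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    coda,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
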