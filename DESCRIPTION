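Package: occuDNA
Title: Multiscale Occupancy Models for Nested Environmental DNA Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hierarchical occupancy models for environmental DNA (eDNA)
    survey data with a nested design of qPCR replicates within water samples
    within sites. Provides qPCR detection calling from threshold cycles and a
    serial-dilution standard curve; a two-level constant occupancy model
    (occurrence psi, per-replicate detection p) fit by maximum likelihood with
    asymptotic standard errors; a three-level Bayesian multiscale occupancy
    model (site occurrence psi, conditional per-sample collection theta,
    conditional per-replicate detection p) with probit-linear covariates fit
    by a conjugate Gibbs sampler; model selection by WAIC and the
    posterior-predictive loss criterion; survey-effort calculators based on
    cumulative detection probabilities; and a synthetic-data generator for the
    three-level Bernoulli process. Ships the field-control and
    salamander-positive-control survey summaries from an eDNA assay validation
    for central Texas Eurycea salamanders as built-in data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
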