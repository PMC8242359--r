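Package: butyrferm
Title: Dose-Response, Batch Fermentation Kinetics and Mutant Screening for
    Butyric Acid Producing Clostridia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Models the strain-improvement pipeline for heavy-ion-mutagenized
    Clostridium tyrobutyricum: a binomial-logistic model of colony lethality
    versus log10 irradiation dose with maximum-likelihood and Bayesian
    (delayed-rejection adaptive Metropolis) fitting; a batch-fermentation
    kinetic model coupling substrate-inhibited (Haldane) growth with product
    inhibition, two-product Luedeking-Piret acid formation and a substrate
    balance with maintenance; least-squares and MCMC parameter estimation
    with posterior predictive envelopes; screening arithmetic for calling
    improved mutants from butyrate/acetate productivity ratios; and seeded
    synthetic-data generators plus packaged reference tables so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
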