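Package: psasim
Title: Quantitative Evaluation of Productivity Susceptibility Analysis by
    Operating-Model Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Maps the ordinal productivity and susceptibility scores of the
    Productivity Susceptibility Analysis (PSA), a qualitative fisheries risk
    assessment framework, onto age-structured fishery operating models with
    Beverton-Holt recruitment. Populations are conditioned to a target
    depletion over a 50-year history and projected 50 years under fixed
    exploitation rates; risk is measured as the probability of spawning
    biomass breaching biomass reference points. The package enumerates all
    scoring permutations, excludes biologically implausible combinations,
    samples a balanced experimental design over the productivity by
    susceptibility grid, and quantifies how well the PSA vulnerability score
    predicts simulated risk (risk-surface similarity via the Frobenius norm,
    LMG relative importance of attributes, pairwise attribute interactions,
    and three-category classification accuracy).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'attributes.R'
    'design.R'
    'popdyn.R'
    'ensemble.R'
    'evaluate.R'
    'lifehistory.R'
    'runner.R'
    'scoring.R'
    'utils.R'
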