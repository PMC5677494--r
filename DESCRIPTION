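Package: marinedisp
Title: Displacement Analysis of Marine Top Predators from Boat-Based
    Line-Transect Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for before-during-after displacement assessment of
    seabirds and marine mammals around offshore developments from
    boat-based line-transect surveys. Implements transect segmentation
    with along-track chainage, assignment of timestamped sightings and
    Beaufort sea-state conditions to fixed-length segments, Bayesian
    negative-binomial and zero-inflated-Poisson generalized additive
    mixed models with phase-varying two-dimensional spatial smooths and
    nested survey/transect random effects fitted by Hamiltonian Monte
    Carlo within Gibbs, posterior prediction surfaces, and
    credible-interval-overlap change maps, together with a synthetic
    survey generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    mgcv,
    jsonlite,
    coda
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
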