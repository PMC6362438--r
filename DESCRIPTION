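Package: hsipm
Title: Habitat- and Age-Structured Integrated Population Models with
    Apparent Immigration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for building and fitting a Bayesian integrated
    population model (IPM) for a territorial bird population breeding in
    two habitat types (Short and Tall ground vegetation) with two adult
    age classes. Combines breeding-success trials, fledgling counts,
    multi-event adult capture-mark-resight histories with state
    uncertainty, single-occasion juvenile recruitment resightings, and
    occupied-territory counts in a state-space model with unconstrained
    year-specific apparent immigration. Includes an individual-based
    simulator that generates all four data streams, a purpose-built
    MCMC sampler with forward-filtering backward-sampling data
    augmentation for the hidden breeder states, transient life-table
    response experiment (LTRE) variance decompositions of the realized
    growth rate, real-time transient elasticities, and habitat
    productivity metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    rjags,
    coda,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
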