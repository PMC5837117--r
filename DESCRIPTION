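Package: iicr
Title: The Inverse Instantaneous Coalescence Rate Under Structured Demographic Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes the inverse instantaneous coalescence rate (IICR) of a
    sample of two haploid genomes under piecewise-constant structured
    demographic models. The IICR is the quantity that sequence-based methods
    such as PSMC estimate; under population structure it traces a
    time-dependent trajectory even when all deme sizes are constant, so it
    must not be read directly as a population-size history. The package
    provides exact curves via the phase-type (absorbing Markov chain)
    representation of the pairwise coalescence time, a native coalescent
    simulator of pairwise coalescence times, the empirical IICR estimator
    from simulated coalescence times, preset model families (n-island,
    1D/2D stepping stone, continent-island, asymmetric gene flow, population
    splits), unit scaling to generations or years, and a log-scale curve
    distance for demographic model exclusion.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    Matrix,
    stats,
    tools,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
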