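Package: acemodel
Title: Accumulated Copying Error Models of Cultural Mutation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the accumulated copying error (ACE) model of cultural
    mutation, in which a continuously valued artifact attribute (such as
    handaxe size) evolves along transmission chains by repeated
    multiplication with independent normal error ratios of mean one.
    Provides closed-form moment predictions, seeded chain-ensemble
    simulation, statistical analysis of transmission-chain experiment data
    (copying-error estimation, normality testing, Monte-Carlo empirical
    p-values), calibration of the model against archaeological
    coefficient-of-variation summaries, and a synthetic-data generator
    emulating an iPad-based image-resizing transmission experiment.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    nortest
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    yaml
Config/testthat/edition: 3
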