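Package: readthru
Title: Local Genetic Context and Logic Phenotypes of a Three-Repressor Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mechanistic modelling of how transcriptional read-through couples
    neighbouring transcriptional units and thereby changes the logic phenotype
    of a fixed-topology three-repressor gene regulatory network (LacI, TetR,
    lambda CI). Provides enumeration of transcriptional-unit order and
    orientation permutations, an ODE steady-state model with orientation-aware
    read-through between adjacent units, logic-gate classification of predicted
    and measured expression profiles, grid-search inference of the
    half-repression point K and read-through rate mu against observed phenotype
    tables, and a seeded synthetic fluorescence generator for end-to-end
    testing of the analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
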