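Package: acetalnet
Title: Reaction-Network Energetics and Kinetics of Xylose Acetalization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing the acid-catalysed acetalization of
    D-xylose with aldehydes as a thermodynamic reaction network. Provides a
    validated data model for species and elementary steps with
    proton-transfer free-energy referencing, cumulative free-energy
    profiles and apparent-barrier (energetic-span) pathway ranking,
    transition-state-theory microkinetic simulation of intermediate
    dynamics, van't Hoff regression of tautomer equilibrium constants,
    conceptual-DFT electrophilicity descriptors of aldehydes, and seeded
    synthetic-data generators so that every stage of the analysis runs
    without external inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
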