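Package: pgcell
Title: Conductance-Based Model of Olfactory Bulb Periglomerular Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reduced six-section compartmental model of olfactory bulb
    periglomerular (PG) interneurons with nine Hodgkin-Huxley style membrane
    mechanisms (fast sodium, delayed-rectifier and A-type potassium,
    calcium-activated potassium, hyperpolarization-activated cation, L- and
    T-type calcium, calcium-activated nonspecific cation, and an ohmic
    nicotinic conductance), a perimembrane calcium shell, and an exponentially
    colored current-noise source. Published maximal-conductance parameter sets
    reproduce the full range of PG electrophysiological phenotypes (simple
    spike trains, low-threshold calcium spikes, plateau potentials) under
    somatic current clamp, purely by rescaling channel expression levels.
    Includes current-clamp protocol simulation, trace analysis (spike,
    sag/rebound, low-threshold spike and plateau detection) and phenotype
    classification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    deSolve,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
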