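Package: rloopkin
Title: Kinetics and Single-Molecule Analysis of Cas9 R-Loop Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for in vitro studies of CRISPR-Cas9 R-loop
    dynamics combining ensemble plasmid-cleavage kinetics and single-molecule
    magnetic tweezers. Fits sequential first-order cleavage models
    (supercoiled to open-circle to linear, optionally preceded by an R-loop
    formation step) to replicate time courses; segments magnetic-tweezers
    bead traces into supercoiling phases and extracts R-loop formation and
    dissociation dwell times; fits single- and two-component exponential
    survival models to dwell-time distributions; sizes trapped R-loops in
    turns and base pairs from paired rotation curves with multiple-comparison
    tests across guide-RNA conditions; and computes the acceptor-ratio FRET
    proxy for ribonucleoprotein loading from paired emission spectra. A
    synthetic instrument-data generator with ground-truth sidecars supports
    validation of every analysis step.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    signal,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
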