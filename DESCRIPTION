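Package: photokie
Title: Oxygen Isotope Fractionation and Kinetic Isotope Effects of
    Photochemical Singlet-Oxygen Pathways
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing oxygen (18O/16O) isotope fractionation of
    dissolved O2 consumed through photosensitized singlet-oxygen (1O2)
    pathways. Implements delta-notation arithmetic and Rayleigh regression
    of enrichment factors, a sensitizer/quencher pre-equilibrium kinetic
    model of O2 consumption with steady-state 1O2 and triplet-sensitizer
    concentrations, forward simulation of isotopologue-resolved O2 loss,
    inference of intrinsic kinetic isotope effects from commitment-masked
    apparent KIEs, the blank/linearity/drift/calibration correction chain
    for raw GC/IRMS delta values, and seeded synthetic-data generators for
    irradiation experiments, control reactors and IRMS sequences.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    ggplot2
Config/testthat/edition: 3
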