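Package: phytoscreen
Title: Suspect and Nontarget Screening of Drug Metabolites in Plant Extracts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for detecting and classifying xenobiotic metabolites in
    plant extracts from high-resolution LC-MS peak data. Implements molecular
    formula arithmetic with monoisotopic masses, isotope-pattern prediction by
    elemental convolution, chlorine-signature nontarget screening,
    biotransformation-rule enumeration of suspect candidates, exact-mass and
    isotope-envelope matching of centroided peak tables, neutral-loss and
    diagnostic-ion annotation of tandem mass spectra, external-calibration
    quantification, and provenance classification of detected species against
    growing-medium and negative controls. A synthetic data generator emulates
    a hydroponic uptake experiment so the whole pipeline is testable without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
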