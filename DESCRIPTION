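Package: pfscreen
Title: PFAS Suspect Screening for Direct-Infusion Ultra-High-Resolution
    Mass Spectrometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated suspect screening of per- and polyfluoroalkyl
    substances (PFAS) in calibrated direct-infusion ultra-high-resolution
    mass spectra. Curates machine-readable suspect lists from molecular
    formulas (monoisotopic and deprotonated masses, single-substitution
    isotopologues, elemental-ratio descriptors, counter-ion stripping for
    salts), reads and merges CASI-windowed centroid peak lists with blank
    filtering, matches measured m/z against suspect masses by nearest
    neighbours within a ppm tolerance, validates annotations with a
    weighted Euclidean isotopologue similarity score, and reduces matches
    to a ranked candidate list via duplicate removal, score thresholding,
    pKa/ionizability and in-source-fragment exclusion, and a composite
    normalized rank. Includes a ground-truthed synthetic-data generator
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    tibble,
    utils
Suggests:
    ggplot2,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
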