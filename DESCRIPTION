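Package: acylsugars
Title: Acylsucrose Structures, Mass Spectral Annotation, Biosynthetic
    Pathway Simulation and ASAT Residue Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for working with the acylated sucroses produced in
    tomato-clade (Solanum) glandular trichomes. Provides a structural
    data model and S n:m nomenclature parser for acylsucroses with F/P
    ring-type classification, exact monoisotopic mass and adduct
    arithmetic with collision-induced-dissociation fragment prediction
    and peak-list annotation, a rule-based simulator of the BAHD
    acylsucrose acyltransferase (ASAT) pathway that reproduces the
    "flipped" reaction order of the pyranose-only pathway, a
    diagnostic-residue classifier that predicts ASAT2/ASAT3 enzyme
    activity types and plant chemotypes from protein sequence, and
    seeded synthetic-data generators for sequences and LC-MS peak
    lists.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
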