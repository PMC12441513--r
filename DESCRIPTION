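Package: herbnet
Title: Molecular Networking and Metabolite Identification for Herbal
    Medicine LC-MS/MS Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated workflow for characterizing the chemical profile
    of multi-herb formulas and their absorbed metabolites from centroided
    UHPLC-HRMS data. Provides exact-mass and adduct m/z arithmetic over
    elemental formulas, MZmine-style chromatogram building and feature
    alignment, feature-based molecular networking with the modified cosine
    similarity, a diagnostic-ion / neutral-loss rule engine for compound-class
    assignment, biotransformation-chain prediction of in-vivo metabolites with
    XIC-based presence calls, and a rule-consistent synthetic-spectrum
    generator for end-to-end validation. Ships curated tables of absorbed
    prototypes and plasma metabolites of the twelve-herb ADHD formula
    AnShenDingZhiLing as worked fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    mzR,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
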