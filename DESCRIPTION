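Package: specfam
Title: Compound-Family Classification and Chemodiversity Analysis for
    DIA Metabolomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reconstructs precursor-linked MS/MS spectra from
    data-independent acquisition (DIA/SWATH) runs by precursor-fragment
    chromatographic correlation, trains and applies a metabolite-family
    classifier built from neutral-loss fragment matrices of annotated
    spectral libraries, and provides the downstream chemodiversity and
    chemotaxonomy statistics: Shannon/Pielou diversity profiles, Fisher
    exact composition tests and relative-frequency shifts, ANOVA with
    Tukey compact letter displays, chemical-ontology roll-ups, and
    comparison of Bray-Curtis/Ward chemotaxonomic dendrograms against
    phylogenies (Mantel, cophenetic correlation, Robinson-Foulds,
    Procrustes). Includes seeded simulators for annotated spectral
    libraries, DIA runs with ground-truth precursor-fragment links, and
    two-condition multi-species abundance studies, so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    ape,
    vegan,
    phangorn,
    multcomp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
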