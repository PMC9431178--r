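Package: clipmatch
Title: NMR Fingerprint Matching and Stereochemistry Enumeration for
    Cyclic Lipodepsipeptides
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the structural characterization and dereplication of
    bacterial cyclic lipodepsipeptides (CLiPs). Enumerates the diastereomers
    of a lipopeptide sequence that are consistent with Marfey's d/l
    composition analysis, constrained by the condensation-domain architecture
    of the producing nonribosomal peptide synthetase (NRPS); classifies CLiPs
    with the (l:m) notation; and decides identity between compounds by
    quantitative matching of their 1H-13C HSQC (C-H)alpha chemical-shift
    fingerprints against a reference library, including a synthetic
    fingerprint generator for validation at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: Metabolomics, Proteomics, StructuralPrediction
RoxygenNote: 7.3.3
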