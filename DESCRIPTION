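Package: glycoEvidence
Title: Diagnostic Validation and Tiered Classification of O-GlcNAc
    Glycopeptide Spectrum Matches
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for evidence-based validation of O-GlcNAc glycopeptide
    identifications from tandem mass spectrometry. Implements monoisotopic
    mass arithmetic for modified peptides, theoretical b/y fragment and
    HexNAc diagnostic-ion modelling (oxonium ions, 203.0794 Da neutral
    loss), MGF peak-list and PSM-table ingestion, tolerance-based peak
    matching, a tiered confidence classifier for peptide-spectrum matches,
    descriptive summaries, hypergeometric over-representation analysis
    with Benjamini-Hochberg FDR binning, two-source ortholog agreement
    accounting, and a seeded generator of synthetic glycopeptide spectra
    for end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'massChem.R'
    'AllGenerics.R'
    'AllClasses.R'
    'annotation.R'
    'fragments.R'
    'spectraIO.R'
    'validator.R'
    'summaries.R'
    'synthetic.R'
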