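Package: photolabelMS
Title: Middle-Down Mass Spectrometry Analysis of Photoaffinity-Labeled
    Receptor Peptides
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to locate neurosteroid photoaffinity-label insertion
    sites on GABA-A receptor transmembrane peptides from middle-down
    LC-MS/MS data. Implements monoisotopic mass bookkeeping and in-silico
    tryptic digestion, MS1-level screening of labeled peptides using the
    delayed-retention criterion and heavy/light isotope-tag doublet
    detection, residue-level adduct localization from b/y fragment-ion
    ladders with neutral-loss handling, labeling-efficiency and
    competition quantification from extracted-ion chromatograms, mapping
    of labeled residues onto structural binding-site clusters, summary
    formulas for two-electrode voltage-clamp electrophysiology, and a
    seeded synthetic LC-MS/MS generator with ground truth so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    pracma,
    Biostrings,
    mzR
Suggests:
    testthat (>= 3.0.0)
biocViews: MassSpectrometry, Proteomics, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
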