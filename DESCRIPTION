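Package: tp53splice
Title: Minigene Splicing-Assay Interpretation and ACMG/AMP Classification of TP53 Exonic Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to interpret minigene splicing-assay readouts for TP53
    exonic variants and fold them into germline variant classification.
    Parses the assay transcript-event nomenclature (exon skipping, partial
    exon deletion, full or partial intron retention) against a TP53
    exon-2..9 gene model, classifies events as frameshift/PTC or in-frame,
    assigns PVS1 (RNA) variable-weight evidence codes from codon-level
    region annotations, interprets SpliceAI delta scores (cutoff binning,
    aberration-type prediction with splice-site competition flagging, and
    predicted-versus-observed concordance), evaluates predictor
    performance, and combines evidence codes under the TP53-specific
    ACMG/AMP points system into five-tier classifications. Includes a
    seeded synthetic-data generator emulating triplicate fragment-analysis
    transcript profiles with a tunable score-expression correlation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
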