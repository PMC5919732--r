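Package: metalscreen
Title: Hit Calling, Enrichment, and Expression Analysis for Metal-Toxicity Modifier Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for arrayed RNAi modifier screens of metal
    (zinc/manganese) toxicity in Drosophila cultured cells and matched bulk
    transcriptomics. Implements plate-average normalization of 384-well
    luminescence readouts, replicate averaging, condition-wide Z-scores,
    reagent- and gene-level hit calling with tiered confidence (two
    concordant dsRNA designs define a high-confidence hit), frequent-hitter
    flagging, replicate-correlation quality control, hypergeometric gene-set
    over-representation with low-to-moderate confidence promotion, an
    FPKM-floored log2 fold-change differential-expression rule with a
    per-replicate cutoff, cross-list overlap reports, expression-evidence
    false-discovery assessment, and seeded generators of synthetic screen
    plates and FPKM tables with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), withr, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
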