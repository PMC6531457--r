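Package: klrpath
Title: Progressive KLR/GPR56 Classification of Human CD4+ Memory T Cells
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Reusable pipeline for defining and validating a progressive
    KLRB1 -> KLRG1 -> GPR56 -> KLRF1 classification of human CD4+ memory
    T cells: single-cell qRT-PCR preprocessing and limit-of-detection
    binarization, bulk intersection differential expression against the
    cell surfaceome, combinational marker gating with cytokine
    quantification, TCR-beta repertoire diversity (Renyi profiles) and
    similarity (Morisita-Horn), density-dependent event downsampling and
    a graph-based pseudotime trajectory. Includes synthetic-data
    generators that emulate all pipeline inputs so every stage is
    testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    limma,
    igraph,
    RANN,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite
Config/testthat/edition: 3
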