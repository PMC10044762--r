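Package: mimnet
Title: Network-Based Phenotype Scoring on Signed Molecular Interaction Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing treatment transcriptomes on curated signed
    molecular interaction maps. Maps time-series differential expression
    results onto a signed directed network of genes and phenotype readout
    nodes, scores inflammatory phenotype activity by attenuated signed path
    propagation with permutation significance, simulates in-silico node
    perturbations, profiles immune cell composition from marker-gene fold
    changes, and extracts phenotype-specific core regulatory networks by
    Pareto-ranked gene-triplet feedback-loop motifs. Includes count
    normalization, PCA outlier screening, a simple differential-expression
    stand-in, and seeded synthetic-data generators with planted ground truth
    for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
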