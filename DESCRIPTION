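Package: retrodyn
Title: Retro-Analysis of Dynamic Transcriptomic Responses to Surgical Stress
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for dynamic (time-course) bulk RNA-seq
    retro-analysis of the acute surgical ("sham") response: simplified
    negative-binomial GLM likelihood-ratio testing across time points with
    Benjamini-Hochberg correction, signed weighted co-expression module
    detection (soft-thresholded correlation, topological overlap, static
    tree cut, module eigengenes), hypergeometric GO enrichment with a
    continuity-corrected module-versus-DET z-score and module-combination
    analysis, transcription-factor target-set over-representation scored by
    the Fisher F-score and a binomial z-score, and layered TF-seeded
    protein-protein-interaction network growth scored by GO-term sensitivity
    and specificity to select the most likely upstream regulatory network.
    Ships a fully self-contained synthetic-data generator with planted
    ground truth emulating a 3 time-point x 8 replicate surgical design.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    SummarizedExperiment,
    Matrix,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
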