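Package: senesig
Title: Consensus Senescence Gene Signatures and Single-Cell Senescence
    Scoring for Endothelial Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Derives consensus up/down gene signatures of endothelial
    cellular senescence from multi-model differential expression,
    benchmarks signatures by preranked permutation GSEA, scores and
    annotates single cells for senescence with a rank-based module score
    and a Gaussian-mixture binary call, predicts knockout-perturbed genes
    from a principal-component co-expression network, and quantifies
    RIP-qPCR fold enrichment by the percent-input delta-delta-Ct method.
    Ships a synthetic-data generator that emulates the multi-donor,
    multi-model bulk design and a staged single-cell lifespan dataset so
    the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    fgsea,
    mclust,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
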