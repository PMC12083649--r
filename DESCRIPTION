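Package: spotscreen
Title: Spatial CRISPR Screen Analysis on Deterministically Barcoded Spot Grids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of spatially barcoded in vivo CRISPR screens:
    declarative read-chemistry models for microfluidic deterministic barcoding,
    mismatch-tolerant demultiplexing of paired-end reads into (spot, sgRNA, UMI)
    records, UMI deduplication and spot-by-sgRNA quantification, spot assignment
    and perturbation-burden statistics, Mixscape-style perturbation signatures
    and score clustering, Wilcoxon differential expression with preranked
    gene-set enrichment, ROC benchmarking of spatial versus pooled sgRNA
    detection, and a ground-truth simulator that emits chemistry-faithful
    FASTQ reads for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    igraph,
    irlba,
    uwot,
    cluster,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
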