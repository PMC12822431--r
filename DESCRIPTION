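Package: tepan
Title: Population-Scale Transposable Element Polymorphism Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds a pan-transposable-element (pan-TE) presence/absence map
    from per-assembly TE annotations and structural-variant (SV) records,
    classifies gene-cluster occupancy across a pangenome with growth-curve
    resampling, dates LTR retrotransposon insertions from terminal-repeat
    divergence, classifies TE effects on nearby gene expression with a
    fold-change rule and cross-stage consistency, runs TE-based GWAS and
    eQTL scans with LD clumping and locus merging, and summarizes haplotype
    combinations of focal insertions against phenotypes and ecotypes. A
    synthetic-data generator with a full ground-truth channel exercises every
    stage without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    edgeR,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
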