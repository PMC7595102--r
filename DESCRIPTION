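Package: mbcsig
Title: Multi-Omic Analysis of Human Memory B Cell Transcriptional Signatures
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Integrative analysis of human naive and memory B cell subsets
    across mRNA, miRNA, lncRNA, immunoglobulin repertoire and chromatin
    accessibility (ATAC) readouts. Implements TMM normalization and an exact
    conditional negative-binomial test for differential expression,
    extraction of a class-switched memory B cell core transcriptional
    signature by intersection of the two vs-naive contrasts with cancellation
    in the isotype contrast, V(D)J assignment with error-corrected somatic
    hypermutation frequencies, differential-accessibility integration with
    expression, miRNA seed-match target-release screening, and lncRNA
    cis/trans co-expression with miRNA sponge detection. A synthetic data
    module generates every input with planted ground truth mirroring the
    study design (four B cell subsets by three subjects), so the whole
    pipeline is exercisable end-to-end without protected human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    tools,
    methods,
    cluster,
    jsonlite,
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    edgeR,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
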