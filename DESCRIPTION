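Package: regmeth
Title: Region-Resolved DNA Methylation and Expression Analysis for Gene
    Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for comparing bisulfite-sequencing methylomes between
    genotypes over gene-anchored windows.  Derives strand-aware upstream
    (200/500 bp) and gene-body regions from a GFF3 annotation, ingests
    per-cytosine methylation call reports (Bismark cytosine/CX layout),
    applies a read-coverage filter, computes weighted methylation levels
    per region and sequence context (CG/CHG/CHH), calls hyper- and
    hypomethylation at percentage-point thresholds, classifies
    expression changes from FPKM tables and qPCR Ct values (2^-ddCt),
    and links methylation calls to expression changes.  A seeded
    beta-binomial simulator generates genomes, annotations, multi-
    genotype cytosine reports and expression tables with planted effects
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    GenomicRanges,
    IRanges,
    methods,
    rtracklayer,
    S4Vectors,
    stats,
    utils
Suggests:
    jsonlite,
    pheatmap,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
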