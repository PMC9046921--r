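Package: popgenscan
Title: Selective-Sweep Scans, Runs of Homozygosity and Linkage
    Disequilibrium from Multi-Sample VCFs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A whole-genome selection-scan toolkit for small resequenced
    cohorts of domesticated diploids.  Reads multi-sample VCFs with a
    sample-to-population map, applies standard SNP quality, spacing and
    depth filters, and computes windowed Weir & Cockerham F_ST together
    with per-population nucleotide diversity (theta-pi) in sliding
    windows to call joint top-quantile candidate sweep regions.  Also
    detects runs of homozygosity with a PLINK-like scanning-window
    algorithm and derives the genomic inbreeding coefficient F_ROH,
    estimates pairwise r^2 by EM over unphased two-locus genotype tables
    to build LD-decay curves, and summarises population structure via
    allele-sharing distances, neighbor-joining trees with bootstrap
    support, and genotype PCA.  A Balding-Nichols simulator with known
    differentiation, injected sweeps, injected autozygosity and
    founder-mosaic linkage provides ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    GenomicRanges,
    IRanges,
    jsonlite,
    rtracklayer,
    S4Vectors,
    stats,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
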