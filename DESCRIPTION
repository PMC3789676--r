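Package: gbsim
Title: Simulation and Analysis of Two-Enzyme Genotyping-by-Sequencing Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to simulate and analyse two-enzyme (PstI/MspI)
    genotyping-by-sequencing (GBS) experiments in biparental recombinant
    inbred line (RIL) populations. Includes a synthetic-data generator
    (reference genome with anchored contigs, F8-derived RILs by single
    seed descent, in-silico restriction digestion, barcoded Illumina- and
    Ion-style reads), exact-match barcode demultiplexing with adapter
    trimming, a k-mer seed-and-extend read placement engine with a
    binomial-likelihood genotype caller (full-read and collapsed-tag
    paths), RIL-specific genotype filters, cross-dataset SNP concordance
    reports, de novo genetic map construction (two-point linkage,
    minimum-spanning-tree marker ordering, Kosambi distances), and
    comparison of genetic against reference-based marker order.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    igraph,
    jsonlite,
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
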