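Package: methseg
Title: Segmentation and Comparative Analysis of Whole-Genome Bisulfite
    Methylomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for contrasting germline and somatic whole-genome
    bisulfite (WGBS) methylomes at cytosine resolution. Implements
    partially-methylated-domain (PMD) detection by 20-kb window
    binarization and a two-state hidden Markov model with multi-sample
    consensus, hypomethylated-region (HMR) calling by a seed-and-extend
    sliding window rule, exact-test differential methylated cytosine
    (DMC) calling with Benjamini-Hochberg correction, observed/expected
    genomic-feature enrichment, satellite-density correlation,
    repeat-element hypomethylation and divergence (age) analysis, and a
    fully seeded synthetic-methylome generator with planted ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    rtracklayer
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
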