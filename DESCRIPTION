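Package: cas9audit
Title: Whole-Genome Off-Target Audit for Cas9-Edited Founder Animals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end audit of Cas9 off-target mutagenesis in
    whole-genome sequencing data from gene-edited founder animals and
    unedited colony controls. Provides bulge-aware enumeration of candidate
    off-target sites for 20-nt protospacers (mismatches plus a single DNA or
    RNA bulge, NGG/NAG PAMs), a de novo variant discovery filter cascade
    (quality thresholds, repeat masking, known-variant removal,
    heterozygous allele-ratio and callable-interval filters, cross-sample
    uniqueness), structural-variant consensus filtering, site-variant
    intersection and classification, on-target deletion confirmation, a
    seeded resampling null for incidental overlap in controls, cohort
    heterogeneity matrices with clustering, and a fully synthetic cohort
    generator with a ground-truth ledger for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Matrix,
    rtracklayer,
    vcfR,
    data.table,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pheatmap
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
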