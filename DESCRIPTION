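Package: domload
Title: Deleterious Mutation Load and Domestication Sweep Analysis for
    Selfing Crop Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying the fate of deleterious mutations during
    crop domestication in predominantly selfing species such as soybean.
    Provides a synthetic wild/domesticated cohort simulator with known
    ground truth, sample- and site-level quality-control filters, windowed
    nucleotide diversity and Tajima's D, linkage-disequilibrium decay,
    ancestral-allele polarization against two outgroups by an
    expectation-maximization estimator, rejected-substitution (GERP-style)
    constraint scoring from multi-species alignment columns with
    reference-sequence projection, per-accession derived-deleterious
    mutation burden with reference-bias correction and group comparisons,
    a cross-population composite-likelihood (XP-CLR-style) selective-sweep
    scan with quantile thresholding and gap-tolerant region merging, and
    pseudodiploid sequence construction for demographic inference in
    selfers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    GenomicRanges,
    IRanges,
    jsonlite,
    pracma,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
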