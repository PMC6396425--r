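Package: ldhic
Title: Comparing Linkage Disequilibrium and Chromatin Interaction Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for the genome-wide comparison of linkage disequilibrium
    (LD) and chromatin contact maps. Computes pairwise r-squared and D-prime
    from phased haplotype panels, calls haplotype blocks with the
    confidence-interval (Gabriel) criterion, performs vanilla-coverage
    normalization and observed/expected transforms of binned Hi-C contact
    matrices, measures multi-scale concordance between strong-LD and
    frequent-contact bin pairs, contrasts interaction-level LD between
    significant and distance-matched non-significant interactions, tests
    whether contact-domain boundaries coincide with LD-block boundaries by
    permutation, and compares eQTL and Gene Ontology enrichment across
    SNP-to-gene mapping strategies. A synthetic-data module generates
    haplotype panels, contact maps, interaction calls and regulatory
    fixtures with planted, machine-readable truth so every analysis can be
    validated end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    data.table,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
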