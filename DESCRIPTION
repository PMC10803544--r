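Package: fcgrdiv
Title: Genotyping and Isoform Profiling of Fc Gamma Receptor Amplicons from
    Long Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Characterizes genetic diversity of Fc gamma receptor (FcgR) genes
    from per-animal long-read amplicon sequencing. Provides gene/isoform models
    with genomic-to-transcript coordinate mapping, a synthetic diploid cohort
    read simulator with known truth, a global affine-gap aligner and threshold
    diploid genotype caller, HGVS-style coding-effect annotation in both
    open-reading-frame and mature-protein numbering, cohort carrier-frequency
    aggregation with retention filtering, expectation-maximization estimation
    of isoform relative abundances, and sequence-level mapping of nonsynonymous
    variants onto receptor domains and Fc-contact interface residue sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    methods,
    Rcpp,
    stats,
    tools,
    utils,
    vcfR,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    pheatmap,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
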