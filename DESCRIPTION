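Package: mitolong
Title: Long-Read Detection and Quantification of Mitochondrial DNA Large Deletions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale toolkit for studying large structural deletions of the
    circular human mitochondrial genome with nanopore-like long reads. Simulates
    reads from heteroplasmic mixtures of wild-type and deleted circular molecules
    under restriction-enzyme linearization (ligation chemistry) or random
    transposase fragmentation (rapid chemistry); aligns them circular-aware with
    k-mer anchoring, gap-tolerant chaining and base-level breakpoint refinement;
    clusters split-read signals into deletion calls with a minimum-support filter;
    estimates deletion heteroplasmy from coverage ratios and junction-spanning
    reads; performs naive pileup point-variant calling with exact binomial
    confidence intervals; and draws Circos-style circular summaries. Reproduces
    the linearization-enzyme bias that arises when a restriction site falls inside
    a deletion, and the resulting protocol-selection workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tibble,
    rlang,
    ggplot2,
    generics,
    Biostrings,
    vcfR,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    rtracklayer,
    BiocGenerics,
    jsonlite,
    optparse
Config/testthat/edition: 3
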