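Package: gxenet
Title: Variance Partitioning, Line-Mean Association and Interaction
    Subnetworks for Inbred Panels Reared Under Two Conditions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain for replicated phenotypes of inbred reference
    panels (such as the Drosophila Genetic Reference Panel) reared under two
    conditions: mixed-model partitioning of phenotypic variance into line,
    line-by-treatment and residual components with broad-sense heritability;
    derivation of viability, development-time and condition-sensitivity
    phenotypes from raw counts; single-marker genome-wide association on line
    means with minor-allele-frequency filtering and variant-to-gene
    annotation; and candidate-gene interaction-subnetwork extraction under a
    one-bridge recruitment rule with a randomization test on the size of the
    largest connected cluster. A synthetic-data generator reproduces the
    statistical structure every stage assumes, so the whole pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    lme4,
    igraph,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    rtracklayer,
    optparse
Config/testthat/edition: 3
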