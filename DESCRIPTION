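Package: seedmix
Title: Mixture Models of Position Weight Matrices for microRNA Seed Families
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Groups fixed-length microRNA seed sequences (nucleotides 2-7 of
    the mature miRNA) into functional families with a multinomial mixture of
    position weight matrices fitted by expectation-maximization. Provides the
    mixture engine with random restarts and likelihood-based selection of the
    number of clusters, two cluster-validation scores (a silhouette score over
    Hamming distances and an information-weighted matrix match score), random
    and average-linkage hierarchical baseline groupings, enrichment of
    reference miRNA families within fitted groups, and a seeded simulator of
    seed sets drawn from a known PWM mixture for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    mclust,
    cluster,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
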