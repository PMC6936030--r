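Package: psiforest
Title: Pseudouridine Site Prediction from RNA Sequence with
    Chemical-Property Features and Random Forests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies RNA pseudouridine (PSI) sites from sequence alone.
    Uridine-centered fragments are encoded with nucleotide chemical
    properties (ring class, functional group, hydrogen bonding) or with two
    comparison schemes (k-spaced nucleotide pair composition, pseudo
    k-tuple nucleotide composition), then classified with a random forest
    tuned by exhaustive grid search under stratified 5-fold
    cross-validation. Includes sensitivity/specificity/accuracy/Matthews
    correlation evaluation, impurity-based feature-importance profiling,
    two-sample-logo per-position enrichment statistics, a seeded synthetic
    benchmark generator, and a command-line interface for scanning whole
    RNA sequences for candidate sites.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    ggplot2,
    jsonlite,
    optparse,
    ranger,
    rlang,
    stats,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
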