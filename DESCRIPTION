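Package: rewire3d
Title: Comparative Analysis of 3D Genome Rewiring Between Paired Conditions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for comparing chromatin organization between two cellular
    states (e.g. a primary tumor and a drug-resistant derivative) from binned
    Hi-C contact matrices together with whole-genome coverage, structural
    variant calls, and differential expression. Implements contact-map
    balancing, distance-decay and differential-decay curves, map-resolution
    checks, stratum-adjusted reproducibility scores, A/B compartment calling
    with saddle-plot strengths and a compartmentalization score, differential
    compartment testing with switch classification, donut-style chromatin loop
    calling with aggregate peak analysis and CTCF convergence annotation,
    insulation-score TAD boundaries, circular binary segmentation of coverage
    log2 ratios, multi-caller structural-variant consensus, permutation-based
    region enrichment, preranked gene-set enrichment, and a gene-level
    multi-evidence importance score. A synthetic-data module generates paired
    condition contact maps and companion omics tables with recorded ground
    truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    jsonlite
Config/testthat/edition: 3
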