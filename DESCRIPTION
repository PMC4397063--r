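Package: panelcov
Title: Capture-Efficiency Evaluation and Coverage Reporting for Targeted
    Sequencing Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quality control of hybridization-capture targeted sequencing
    panels. Computes native per-base depth over a BED-defined target from
    BAM/SAM alignments, derives per-sample enrichment metrics (on-target
    read percentage, mean base coverage, percentage of bases reaching a
    depth threshold, and enrichment stability at 0.2 times the mean
    depth), aggregates metrics over pre-enrichment pools, evaluates
    multiplex index balance, checks genotype concordance against
    SNP-array calls, and renders per-gene/per-exon coverage reports with
    failing-exon detection. Ships a deterministic fixture generator
    (alignments, target designs, genotype tables) with analytically known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    IRanges,
    Rsamtools,
    jsonlite,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
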