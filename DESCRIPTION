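Package: admixlocus
Title: Local-Ancestry Post-Processing and Locus-Specific Enrichment for
    Admixed Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Post-processes haplotype-level local-ancestry posteriors
    (RFMix v1 style forward-backward and Viterbi files) into per-variant
    cohort ancestry summaries for three-way admixed cohorts, finds
    same-chromosome SNP pairs within a genetic-distance window (bracket
    search, default +/- 0.5 cM), draws seeded random-control SNP panels,
    classifies loci by dominant-ancestry threshold and compares target
    versus control panels with chi-square or Fisher's exact tests. Ships
    a single-pulse admixture-mosaic simulator that emits the same file
    dialect with ground-truth tracks, so the full pipeline is testable
    without genotype data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
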