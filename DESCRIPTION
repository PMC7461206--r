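Package: pgfam
Title: Gene Family Expansion and Expression Divergence Analysis
Version: 0.1.0
Authors@R:
    person("PG", "Family Tools", email = "pgfam@example.org", role = c("aut", "cre"))
Description: Tools for analysing the expansion and expression divergence of a
    plant gene family (modelled on the GH28 polygalacturonases) across a
    diploid reference species and a descendant shaped by whole-genome
    triplication. Implements conserved-domain family identification,
    exon/intron architecture and intron phases, neighbor-joining phylogenies
    with Poisson-corrected pairwise-deletion distances and bootstrap supports,
    minimal ancestral-gene counting with per-clade gain/loss tables,
    tandem-duplicate detection under the 80/80 rule, Nei-Gojobori (NG86)
    Ka/Ks, subgenome retention arithmetic, 2^-delta-delta-Ct expression
    matrices with paralog-pair divergence categories, and IUPAC consensus
    promoter scanning. Ships a seeded two-species gene-family simulator with a
    complete ground-truth ledger so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    Biostrings,
    rtracklayer,
    BiocGenerics,
    GenomicRanges,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
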