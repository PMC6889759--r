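Package: panagrokit
Title: Comparative Genomics of Ploidy, Horizontal Gene Transfer and
    Divergence Age in Panagrolaimid Nematodes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the comparative-genomic characterisation of
    parthenogenetic, cryptobiotic panagrolaimid nematodes and similar
    systems. Infers ploidy from variant (allele) frequency spectra,
    screens proteomes for horizontal gene transfer with the Alien Index
    and an evidence cascade (introns, genomic neighbourhood, expression),
    reconstructs the gain and loss of horizontally acquired gene families
    on a species tree under Dollo parsimony, discriminates allopolyploid
    from autopolyploid origin of duplicated gene copies by duplication-loss
    gene-tree reconciliation against donor-graft hypotheses, converts
    genome-wide distances into divergence ages calibrated by a reference
    split and generation times, and provides domain-enrichment and 2x2
    contingency statistics. Includes seeded generators of synthetic
    variant tables, hit tables, presence/absence matrices and gene trees
    so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    rtracklayer,
    vcfR,
    withr,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
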