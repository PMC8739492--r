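Package: palcolin
Title: Co-Linear Assembly and Retrobiosynthesis of Trans-AT PKS-NRPS Gene Clusters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for motif-based domain classification, forward co-linear
    assembly of polyketide structures from hybrid trans-AT PKS-NRPS module
    architectures, reverse (retrobiosynthetic) architecture prediction with
    congruence scoring, distance-based phylogenetic classification of carrier
    proteins, and mapping of multi-copy biosynthetic gene cluster variants to a
    macrolide compound family.  Ships architecture and structure fixtures for
    the five palmerolide (pal) biosynthetic gene clusters and the palmerolide
    A-H family, plus seeded generators for synthetic architectures, motif
    labelled proteins, and Jukes-Cantor evolved alignments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    Biostrings,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
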