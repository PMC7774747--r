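Package: evosubtype
Title: Evolutionary Subtyping of Tumors from Multi-Region Mutation Phylogenies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs per-patient tumor phylogenies from multi-region
    somatic mutation tables by Dollo parsimony with a normal outgroup, encodes
    each tree as a normalized edge-length vector on a reference bifurcated
    tree, clusters patients into evolutionary subtypes by hierarchical
    clustering with silhouette-based model selection, and derives downstream
    statistics: intra-tumor heterogeneity indices (branched diversity, ITH
    index, copy-number ITH, subclonal-diversity curves), early driver feature
    (EDF) genes with Bradley-Terry temporal ordering, mutual exclusivity and
    co-occurrence of driver genes, and subtype-phenotype associations
    (Kaplan-Meier/log-rank, Mann-Whitney). Includes a synthetic multi-region
    cohort generator with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    survival,
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    cluster,
    mclust,
    phangorn,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
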