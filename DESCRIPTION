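Package: miremap
Title: Reconstruction of miRNA-Mediated Regulatory Networks from
    Two-Platform miRNA Profiling
Version: 0.1.0
Authors@R:
    person("miremap", "developers", email = "miremap@example.org",
           role = c("aut", "cre"))
Description: Reconstructs miRNA-mediated regulatory networks from
    cross-platform miRNA profiling (qPCR OpenArray-style Ct tables and
    small RNA-Seq counts), gene expression fold changes, and curated
    TF-miRNA and miRNA-target interaction resources.  Implements
    fold-change differential-expression calling with cross-platform
    intersection, a desk-scale small-RNA read quantifier, promoter-window
    mapping of ChIP-Seq peaks to miRNA loci, inverse-expression filtering
    of curated miRNA-target interactions, network statistics (hubs,
    combinatorial regulation, co-targeting, chromosomal clustering), and
    Fisher-exact over-representation analysis.  A seeded synthetic-data
    generator with planted ground truth makes every stage testable
    without external downloads, and reference tables from a Mir122a
    knockout mouse liver study ship as plain-text fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    data.table,
    igraph,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
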