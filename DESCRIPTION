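Package: twinquad
Title: Discordance Analysis of Monozygotic Twin Quad Genomes
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing the genomes of a monozygotic twin pair and
    their parents (a family quad). Small sequence changes (SNVs, indels,
    block substitutions) are filtered to high confidence, partitioned into
    shared and unshared with the co-twin, and classified as inherited or
    post-zygotic de novo by presence in the parents; copy-number and
    structural variants are matched across samples with a 50 percent
    reciprocal-overlap rule (breakpoint-distance and orientation rules for
    inter-chromosomal events and inversions) and classified the same way.
    Affected genes are annotated for region and translational impact,
    tested for pathway over-representation with a right-tail
    hypergeometric test, and the per-individual top-ranked pathways are
    compared under a liability-threshold model that separates shared
    genetic predisposition (GP) from affected-twin-specific disease
    pathways (GPD). A synthetic quad-genome simulator with ground-truth
    origin labels and a mosaicism dropout model makes every stage testable
    without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    jsonlite,
    yaml,
    igraph,
    vcfR,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
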