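Package: heurosplice
Title: Data-Driven Heuristics for Splice-Altering Variant Assessment
Version: 0.1.0
Authors@R:
    person("heurosplice", "developers", email = "heurosplice@example.org",
           role = c("aut", "cre"))
Description: A rule-based engine for assessing putative splice-altering
    variants (SAVs). Implements a splicing-requirements checklist for
    splice-site viability (donor/acceptor motifs, polypyrimidine tract,
    branchpoint spacing, AG-exclusion zone, intron and exon length minima),
    decision-tree classification of donor- and acceptor-disrupting variants
    into heuristic subgroups with quantified spliceogenicity (the proportion
    of variants in a context that alter splicing), mechanism attribution and
    partner-site search for deep-intronic pseudoexon-creating variants, and
    re-estimation of spliceogenicity and splicing-outcome statistics from
    labeled variant evidence tables. Ships a first-order position-weight
    splice-site scoring model and an optional plug-in for externally supplied
    maximum-entropy score matrices, plus a deterministic synthetic-data
    generator so the whole engine is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    VariantAnnotation,
    SummarizedExperiment,
    data.table,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
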