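Package: belhier
Title: Hierarchical Sequence Labeling for BEL Statement Extraction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts causal-network statements in the Biological Expression
    Language (BEL) from biomedical sentences by hierarchical sequence
    labeling.  Provides BEL statement parsing, normalization, unification and
    arity-marked preorder serialization; biomedical tokenization and entity
    anonymization; dictionary-based entity grounding by edit distance;
    dependency-tree sentence simplification; an IBM Model 1 expectation
    maximization word aligner with pseudo-parallel augmentation; layered
    BIESO tag generation and tree reconstruction; stacked linear-chain
    conditional random field labelers; multi-level precision/recall/F1
    scoring; and a seeded synthetic corpus generator so the whole pipeline is
    testable without external corpora.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
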