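Package: stemtrace
Title: Prioritizing the Normal Cell of Origin of Cancer Subtype Stem Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Implements a pipeline for prioritizing the normal cell of origin
    of cancer-subtype stem cells from expression signatures. Candidate normal
    populations are scored against each stem-cell signature by four concordance
    measures (hypergeometric signature overlap, a fold-change-weighted gene
    signature score, Lin/best-match-average ontology semantic similarity, and
    mean shortest-path proximity on a protein interaction network); the eight
    resulting rank lists (up and down directions) are fused per subtype with an
    order-statistics Q statistic and averaged across datasets into an overall
    rank. Downstream stages detect correlation-coherent network modules on a
    functional-interaction network and scan promoter sequences with TRANSFAC
    position weight matrices using Match-style matrix and core similarity
    scores. A synthetic-data generator with planted ground truth makes every
    stage testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
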