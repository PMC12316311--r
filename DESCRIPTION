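Package: rponscan
Title: Inference of Bacterial Sigma-54 (RpoN) Regulons from Genome Sequence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genome-scale inference of the bacterial sigma-54 (RpoN)
    regulon. Implements seed position-weight-matrix modelling of the bipartite
    -24/-12 promoter elements, iterative pattern-finding/pattern-discovery
    cycles with exact score p-values and E-value thresholds calibrated by
    Matthews correlation, operon-expanded hypergeometric enrichment of COG
    functional groups per taxonomic class, a six-step classifier for
    sigma-54-specific enhancer-binding proteins (GAFTGA motif architecture),
    and an RpoN domain-architecture census. Ships a synthetic-data generator
    that plants promoters, operon structure, COG enrichment and EBP motif
    architectures with recorded ground truth, so the whole pipeline is
    testable end to end without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
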