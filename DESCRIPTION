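Package: topoprofile
Title: Topology-Based Gene Expression Profiling and Tumor Subtype Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies tumor subtypes from gene expression matrices using
    persistent homology on correlation-distance point clouds. Genes with
    bimodal expression are screened with a scale-invariant width statistic
    (variance over squared mean absolute deviation), grouped into coherent
    panels via size-constrained zero-dimensional persistence barcodes, and
    used to hierarchically bisect samples into tightly correlated core
    groups. A nearest-core-group predictor assigns new samples by mean
    correlation distance against per-group radii. Includes exact Betti
    number computation over GF(2) for simplicial complexes and seeded
    synthetic-data generators with planted subtype structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    igraph,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
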