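Package: svgclust
Title: Spatially Variable Gene Detection, Pattern Clustering and Spatial
    Domain Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects spatially variable genes (SVGs) in spatial
    transcriptomics data with a multi-kernel variance-component score test
    (Gaussian and Cosine kernel bank, Davies/Imhof weighted chi-square tail,
    Cauchy p-value combination, Benjamini-Hochberg selection), groups the
    detected SVGs by spatial expression pattern via covariate-adjusted
    retesting and Leiden community detection on a gene dependency graph,
    and uses per-cluster spatially aware embeddings for spatial domain
    detection. Includes simulation generators for correlated gene modules
    and layered cortex-like tissue, evaluation metrics (adjusted Rand
    index, percentage of abnormal spots, empirical power and FDR), and a
    command-line interface over the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    mclust,
    data.table,
    withr,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
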