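Package: anchorDeconv
Title: Anchor-Gene Discovery and Marker-Driven Deconvolution of Bulk
    Expression Mixtures
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Unsupervised discovery of distinguisher (anchor/marker) genes
    from linear-scale bulk gene-expression matrices by greedy extreme-point
    selection in the gene-gene conditional-expression geometry, without ever
    materialising the gene-by-gene matrix.  The anchors seed a complete
    deconvolution: alternating non-negative least squares estimates both the
    per-sample composition of biological processes or cell types and their
    pure expression signatures.  Includes a mixture simulator (fixed mixing
    tables or Dirichlet proportions, multiplicative log-normal noise),
    evaluation metrics with permutation alignment, and a command-line entry
    point.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    optparse,
    withr
Suggests:
    SummarizedExperiment,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
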