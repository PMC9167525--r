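Package: coexphys
Title: Co-Expression Network Modules Linked to Physiological Traits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline relating gene expression variation to
    whole-organism physiology. From a gene-by-sample count matrix plus
    per-sample physiological traits it performs median-of-ratios
    normalization and count filtering, simplified negative-binomial GLM
    differential expression with Benjamini-Hochberg correction and
    adaptive-pattern classification across populations, weighted
    co-expression network construction (soft thresholding, topological
    overlap, dynamic tree cutting, eigengene merging), module
    eigengene-trait correlation with jack-knife robustness screening and
    multiple correlation, and hypergeometric term over-representation.
    Includes a synthetic count and trait generator with planted modules
    and recorded ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    Matrix,
    withr,
    yaml
Config/testthat/edition: 3
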