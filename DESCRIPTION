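Package: glcmbayes
Title: Bayesian Tree-Network Profiling of Gray-Level Co-Occurrence Texture Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts gray-level co-occurrence matrix (GLCM) texture features from
    two-class grayscale images, ranks them by class-separating relative entropy,
    discretizes them, learns a tree-structured (Chow-Liu) Bayesian network by
    maximum-weight spanning tree over pairwise mutual information, and performs
    exact inference on the tree to produce arc-strength and node-force reports,
    tornado sensitivity analyses, greedy dynamic profiles with Bayes factors,
    evidence optimization trees, segment profiles with frequentist and Bayesian
    (BEST) two-group tests, and target-prediction performance reports. Includes
    synthetic-data generators (Gaussian-smoothed noise textures, tree-structured
    discrete samplers, correlated feature tables) for validation without any
    imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    png,
    tiff,
    MASS,
    pROC
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
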