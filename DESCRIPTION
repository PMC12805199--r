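Package: pairdif
Title: Group-Pairwise Regularized Differential Item Functioning Detection
    for Multi-Group 2PL Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects differential item functioning (DIF) in multi-group
    two-parameter logistic (2PL) item response models without designating a
    reference group. Item-parameter differences between every pair of groups
    are penalized with a truncated L1 penalty (TLP), estimated by marginal
    maximum likelihood with an EM algorithm using Gauss-Hermite quadrature,
    and optimized by difference-of-convex programming with ADMM splitting.
    Groups sharing an item parameter are collapsed with a union-find
    structure, tuning parameters are selected by BIC over a grid, and a
    synthetic-data generator with pairwise true/false positive rate scoring
    supports simulation studies of balanced and unbalanced group designs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
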