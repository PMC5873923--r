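Package: kernGE
Title: Kernel Models for Multi-Environment Genomic Prediction with
    Genotype-by-Environment Interaction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bayesian multi-environment genomic prediction with linear (GBLUP)
    and Gaussian marker kernels. Fits the Hadamard-product family of models
    (main genetic effect, single-variance and environment-specific G-by-E
    deviations, with or without an iid per-line random intercept) by Gibbs
    sampling in kernel-eigenbasis coordinates, and the Kronecker-structured
    unstructured-covariance models that allow negative genetic correlations
    between environments. Includes marker quality control, CV1/CV2
    cross-validation with per-environment Pearson accuracy, and a synthetic
    multi-environment trial generator with known ground truth for parameter
    recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
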