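Package: kinblend
Title: Multi-Trait Genomic Prediction with Blended Pedigree-Genomic Kinship
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Multi-trait genomic best linear unbiased prediction (GBLUP)
    with a kinship kernel formed as a convex combination of the pedigree
    numerator relationship matrix A and a genomic relationship matrix G
    (VanRaden or Forni form, optionally min-max rescaled to the [0, 2]
    range of A), K = lambda * G + (1 - lambda) * A. Provides restricted
    maximum likelihood (REML) estimation of among-trait genetic and
    residual covariance matrices under the Kronecker-structured
    multivariate model, prediction of breeding values by the conditional
    mean, repeated random-split cross-validation of predictive ability
    over a grid of blending weights, expected versus realized genetic
    regressions between traits, and a pedigree/gene-dropping simulator
    with known trait architecture for validating the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    MASS,
    pracma,
    withr,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
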