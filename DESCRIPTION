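Package: metapart
Title: Variation Partitioning of Pond Metacommunities with Generalized
    Additive Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies environmental versus spatial control of
    metacommunity structure from site-by-taxon presence-absence matrices.
    Binary community matrices are reduced with binomial generalized
    linear latent variable models selected by AIC, and the predicted
    occurrence probabilities are partitioned between environmental
    principal components and spatial coordinate smooths using
    quasibinomial generalized additive models with forward selection
    under a double-stopping criterion.  The environmental component is
    corrected for spatial autocorrelation by Moran spectral
    randomization over a distance-based Moran eigenvector map basis, and
    environmental heterogeneity between regions is contrasted with
    permutation tests of multivariate dispersion (PERMDISP).  A
    synthetic metacommunity generator with known environmental and
    spatial effect sizes makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    mgcv,
    vegan,
    geosphere,
    jsonlite,
    stats,
    utils
Suggests:
    ape,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
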