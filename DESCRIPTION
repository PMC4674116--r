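Package: craniomorph
Title: Craniometric Size/Shape Decomposition and Multivariate Analysis of
    Otter Skull Form
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for traditional (distance-based) craniometrics of
    carnivoran skulls, built around the comparison of mouth-oriented and
    hand-oriented feeding specializations in otters. Provides a 25-trait
    measurement registry with bilateral averaging and validation,
    maximum-likelihood (EM) imputation of sparsely missing measurements
    under a grouped multivariate log-normal model, Mosimann-style
    decomposition of log form into geometric mean size and log-shape
    ratios with covariance principal components, Wilks' lambda MANOVA
    with Rao's F approximation and partial eta squared, canonical and
    multivariate-regression ordination, equal-prior linear discriminant
    analysis with leave-one-out cross-validation, functional jaw indices
    (mandibular bluntness, masseter and temporalis mechanical advantage,
    size-adjusted occlusal surface area), and a synthetic skull
    generator so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
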