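Package: morphodist
Title: Multivariate Morphological Resemblance for Mixed-Scale Artefact Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies multivariate resemblance among objects described by
    mixed continuous, ordinal and nominal attributes with missing values, as
    used in attribute-based analyses of unretouched lithic flakes. Provides a
    declarative variable schema with geometric-mean size correction,
    heterogeneous (Pearson/polychoric/tetrachoric/polyserial/biserial)
    correlation matrices, a resemblance procedure combining multiple
    imputation, mixed-data principal component analysis and Mahalanobis-type
    distances into median distance matrices with confidence bounds, and
    permutation inference on distance matrices (PERMANOVA, PERMDISP, principal
    coordinates, balanced pairwise contrasts with Bonferroni correction). A
    synthetic-assemblage generator with known group structure supports
    calibration and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    ape,
    ggplot2
Config/testthat/edition: 3
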