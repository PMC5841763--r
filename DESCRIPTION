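Package: traitrange
Title: Local Trait Variability and Geographic Range Size of Congeneric Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for testing whether locally expressed intraspecific
    variability in functional traits predicts the geographic range size of
    tropical tree species, using congeneric pairs of one narrow endemic and
    one widespread species. Implements occurrence-record cleaning and
    alpha-shape (alpha-hull) extent-of-occurrence estimation under a Lambert
    azimuthal equal-area projection, sample-size-corrected coefficients of
    variation, multivariate functional dispersion in principal-component
    space, hierarchical (genus/species/tree/leaf) variance decomposition via
    nested random-effects models, environmental residualization of trait
    values, paired congeneric mixed-model tests with likelihood-ratio
    inference, Mantel tests, and a synthetic-data generator with known ground
    truth for end-to-end validation of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    lme4,
    geosphere,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mgcv,
    vegan,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
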