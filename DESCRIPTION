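Package: crownzoi
Title: Spatially Extended Zone-of-Influence Neighborhood Models for Trees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for fitting spatially extended ("zone of influence")
    neighborhood competition models to stem-mapped forest census data.
    Tree crowns are represented as weighted random point clouds derived
    from a crown-radius allometry, with crown plasticity emulated by
    removal or relocation of points shaded by larger neighbors.
    Conspecific and heterospecific basal-area predictors are accumulated
    over grids of neighborhood radii and overlap tolerances, and fed into
    per-species growth (least squares) and survival (logistic) regressions
    that are summarized by AICc model averaging. Community-level syntheses,
    location-randomization null tests, and a synthetic-forest generator
    for validation are included.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tools,
    MASS,
    pracma,
    vegan,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
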