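Package: reburnscape
Title: Short-Interval Fire (Reburn) Dynamics in Boreal Landscapes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify short-interval fire (reburn) dynamics from
    annual burn-severity rasters: per-point burn histories on a uniform
    sampling lattice, burn and reburn fractions with fire-interval
    empirical distribution functions, a randomized-placement null model
    for the reburn proportion expected in the absence of post-fire
    negative feedbacks, robust Theil-Sen and weighted least-squares trend
    estimation with a Box-Pierce autocorrelation pre-check, landcover
    collapse and conifer reburn-share trends, and random-forest
    classification of reburn locations with conditional permutation
    variable importance.  A stochastic fire-landscape simulator with a
    tunable post-fire refractory feedback provides a fully synthetic
    test-bed for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tiff,
    randomForest,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
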