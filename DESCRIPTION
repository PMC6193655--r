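Package: soilfertmap
Title: Hybrid Geostatistical Mapping of Soil Chemical Properties and Fertility
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for mapping soil chemical properties and an integrated
    soil-fertility index over hilly terrain with hybrid geostatistics:
    empirical semivariogram estimation and model fitting (spherical,
    exponential, Gaussian, linear), ordinary kriging, and regression kriging
    with a stepwise terrain-covariate drift; leave-one-out cross-validation
    with per-property method selection; twelve DEM-derived terrain covariates
    (slope, aspect, wetness and stream-power indices, relative position index,
    and others); and an improved minimum-based Nemerow comprehensive fertility
    index with grade mapping. Includes a seeded synthetic-landscape generator
    so the whole workflow can be exercised and validated without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    e1071,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    car,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
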