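Package: bloomsat
Title: Satellite Flowering Phenology from Blossom Detections
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects clumped magenta tree blossoms in 4-band reflectance
    scenes with a small convolutional patch classifier, spatialises
    detections to a coarse presence grid, models per-pixel flowering
    seasonality with a constrained three-harmonic model fitted by weighted
    least squares, extracts flowering start/peak/end events, clusters
    phenological populations with K-means, and tests spatial association
    between presence and environmental covariates with a decile-class
    bootstrap null. A seeded synthetic-world generator emulates the imagery
    and covariates so the whole pipeline runs self-contained.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
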