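Package: adeliescan
Title: Detection-Corrected Abundance Estimation for Penguin Colonies in
    Medium-Resolution Multispectral Imagery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for surveying colonial breeders (Adelie penguins) in
    medium-resolution multispectral satellite imagery and correcting the
    resulting regional abundance estimates for size-dependent non-detection.
    Implements a one-class ellipsoid (Mahalanobis) classifier for guano
    pixels, connected-component extraction of candidate colonies, a
    logistic size-dependent detection model, a Poisson offset regression
    converting guano area to breeding pairs via an apparent density, a
    lognormal colony-size law whose convolution with non-detection yields
    the expected size of a missed colony, a Negative Binomial model for the
    number of missed colonies, and bootstrap scaled-difference equivalence
    testing across spatial scales of aggregation. A synthetic-scene
    generator with truth masks makes the whole pipeline testable without
    any satellite download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    EBImage,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    readxl
Config/testthat/edition: 3
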