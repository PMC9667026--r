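Package: ovimetry
Title: Non-Contact Sheep Morphometrics from Silhouette Images and Body-Weight Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Computes ovine body-size traits from segmented silhouette images and
    relates them to body weight. Detects anatomical landmarks (withers, hip top,
    sciatic tuberosity, chest bottom, shoulder and rump edges, shank) on binary
    side- and dorsal-view masks using convex-hull range restriction, point-to-line
    distance rules and u-chord (Menger) curvature; converts pixel lengths to
    centimetres through distance-dependent quadratic scale models fitted to
    calibration-plate samples; derives the eight standard traits including an
    elliptic-integral chest circumference; and provides the biometric layer:
    descriptive statistics, Spearman correlation, one-way ANOVA by sex, ordinary
    least squares and bidirectional stepwise selection for body-weight prediction.
    A synthetic-silhouette generator with known ground truth supports end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    jsonlite,
    png,
    pracma,
    EBImage,
    MASS,
    generics,
    stats,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
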