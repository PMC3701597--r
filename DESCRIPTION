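Package: fishpass
Title: Underwater Video Fish Counting and Factorial Trawl Count Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for counting and identifying fish that pass through an
    open-ended imaging chamber mounted in place of a trawl codend. Provides a
    ground-truthed synthetic video generator (fish-like silhouettes moving
    through a fixed viewing chamber under configurable turbidity and noise),
    a detection and tracking pipeline (temporal-median background estimation,
    gradient-confirmed foreground segmentation, constant-velocity
    nearest-neighbour tracking), silhouette shape descriptors (Hu moments,
    aspect ratio, ellipse defect, normalized-template RMS error, radial
    outline pattern), an SVM species identifier with per-object confidence and
    k-fold evaluation protocols, per-sample count and density summaries for
    factorial trawl surveys, and a from-scratch suite of count regression
    models with a log-volume offset (Poisson, quasi-Poisson, negative
    binomial, zero-inflated negative binomial) with AIC-based comparison,
    dispersion diagnostics, and exact and Monte-Carlo power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    png,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    glmmTMB,
    optparse
Config/testthat/edition: 3
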