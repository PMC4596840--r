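Package: trichor
Title: Orientation Vector-Field Modelling of Insect-Wing Microtrichia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the local orientation of microtrichia (small hair-like
    cuticular projections) on insect wings as a weighted sum of three
    antiwetting strategies: pointing upslope toward the nearest ridge peak,
    pointing toward the nearest wing edge, and pointing distally away from
    the body. Provides planar nearest-feature geometry on digitized wing
    margins and ridge polylines, brute-force two-parameter calibration of
    the weighting factors against quadrat-sampled hair orientations,
    circular-statistics summaries, exact binomial tests of directional
    bias, model-fidelity metrics, and reduction of drop rolloff-angle
    assays to a directional force-of-retention ratio. A seeded synthetic
    wing generator makes every stage testable without specimen data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    mgcv,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
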