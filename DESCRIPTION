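Package: coastcore
Title: Small-Sample Coastal Species Distribution Modelling and
    Conservation Decision Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable blueprint for presence-background species
    distribution modelling of near-shore island endemics with few,
    spatially clustered records.  Generates synthetic volcanic-island
    test landscapes, derives terrain and coastal-exposure predictors
    from a digital elevation model, fits an L1-regularised
    maximum-entropy (MaxEnt-style) model with linear, quadratic and
    hinge features, validates it with leave-one-cluster-out spatial
    holdout (AUC, high-specificity partial AUC, relative RMSE), and
    converts continuous suitability into regulation-ready core-habitat
    maps via a conservative threshold menu, coastal-belt and
    minimum-mapping-unit filters, leakage accounting, and
    sensitivity-driven area bands.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    boot,
    dplyr,
    EBImage,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
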