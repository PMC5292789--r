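Package: eq5dmap
Title: Mapping EQ-5D Utilities to Global Burden of Disease Disability Weights
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores EQ-5D-5L health-state responses into utilities through a
    pluggable 5L-to-3L crosswalk and an additive 3L tariff (value sets are
    data files), and maps utilities to Global Burden of Disease (GBD)
    2010/2013 disability weights with an anchored locally weighted polynomial
    regression on the logit scale. Includes the descriptive and inferential
    comparison statistics used in burden-of-disease valuation studies
    (Spearman rank correlations with exact permutation p-values, paired
    t-tests, complement-difference and severity-rank tables, dimension-level
    frequency tables), a latent-variable generator of synthetic ordinal
    EQ-5D responses, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
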