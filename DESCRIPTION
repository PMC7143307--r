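Package: oliveASLT
Title: Accelerated Shelf-Life Testing Kinetics for Olive Oil Quality Indices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for accelerated shelf-life testing (ASLT) of extra-virgin
    olive oil and similar lipid matrices. Estimates apparent zero-order
    oxidation rate constants from storage time-series of quality indices
    (K270, conjugated trienes, hexanal, pyropheophytin a, peroxide value and
    others), models their temperature dependence with a reparametrized
    Arrhenius equation, and converts fitted models plus regulatory
    acceptability limits into shelf-life predictions and shelf-life plots.
    Includes a synthetic storage-study generator for validating the full
    pipeline against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    readr,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown,
    withr
Config/testthat/edition: 3
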