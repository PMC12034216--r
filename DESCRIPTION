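Package: rotsoc
Title: Crop Rotation Effects on Soil Organic Carbon Stocks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how corn-soybean rotation sequences relate to soil
    organic carbon (SOC) stocks. Generates synthetic site tables, multi-year
    categorical crop rasters and monthly weather with known ground truth;
    classifies three-year rotation sequences (0c-3c) from rasters at point
    locations; builds windowed warm/cold-season climate covariates; fits
    log-linear fixed-effects regressions with percent-effect transforms and
    one-tailed Welch tests; estimates rotation-pattern area shares by seeded
    raster sampling; and runs area-weighted carbon conversion scenarios with
    social-cost-of-carbon valuation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    sandwich,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
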