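Package: wheatpb
Title: Soil-to-Wheat Lead Transfer Models, Cross-Cultivar Extrapolation and
    BAF Normalization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling the transfer of lead (Pb) from soil to wheat
    grain. Computes bioaccumulation factors (BAF = grain Pb / total soil Pb),
    fits log-linear transfer models of log10(BAF) on soil pH and log10(organic
    carbon) with stepwise predictor selection, extrapolates a fitted model to
    non-modeled cultivars by refitting only the intercept (intrinsic
    sensitivity) against linear-scale squared error, normalizes BAFs to
    reference soil scenarios, quantifies the resulting reduction in
    intra-species variability, and validates predictions against a two-fold
    interval. Includes a seeded pot-experiment simulator with pH-class
    dependent Pb dosing so the whole pipeline is testable without external
    data.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
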