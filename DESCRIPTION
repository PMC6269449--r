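Package: bnfcurve
Title: Seasonal Dynamics of Biological Nitrogen Fixation in Soybean from
    Stem Ureide Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify seasonal biological nitrogen fixation (BNF)
    in soybean from the relative abundance of ureides (RAU) in stem tissue.
    Converts stem ureide/nitrate assays and daily weather into RAU and
    cumulative thermal time, fits the three-parameter beta growth function
    to seasonal RAU trajectories, derives traits (maximum rate, t0.5, area
    under the curve), compares nitrogen treatments with small-sample AICc,
    removes phenology trends from agronomic traits with continuous bilinear
    (broken-stick) regression, and regresses the residuals on RAU at the
    full-seed stage at the mean and at boundary quantiles. Includes a
    calibrated synthetic multi-environment trial generator so the whole
    pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    minpack.lm,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
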