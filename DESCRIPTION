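Package: nanoforesight
Title: Horizon-Scanning Prioritization for Nanotechnology-Enabled Health Products
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for the prioritization stages of a Horizon
    Scanning exercise on nanotechnology-enabled health products (NHPs).
    Starting from a curated database of detected signals (literature, patent
    and clinical-trial records classified with a four-position NHP signature
    and one or more design-solution codes), the package builds design-solution
    frequency spectra, computes novelty scores S = (T - C)/T * 10, selects
    trends (weak signals) and tentative wild cards by quartiles of the
    cumulative frequency distribution, enriches tentative wild cards with
    multiplicative correction factors, and assesses prioritized items against
    a table of regulatory documents to flag insufficiently regulated
    categories. A synthetic-data generator reproduces the statistical
    structure of the study conditions so that every stage is testable without
    any external download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    readr,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
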