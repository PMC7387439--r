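Package: nanosip
Title: Single-Cell Stable Isotope Probing Analysis for NanoSIMS Ion Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying single-cell anabolic activity from
    nanometer-scale secondary ion mass spectrometry (NanoSIMS) ion-count
    images of microbial cells incubated with 13C- and 15N-labeled
    substrates. Provides scan alignment and drift correction, per-cell
    (region-of-interest) isotope-ratio and atom-fraction measurement,
    instrumental mass fractionation calibration, activity classification
    against membrane-background thresholds, biomass-based growth rates
    and doubling times, substrate-incorporation-based biomass generation
    rates, inference of the originally active fraction of a community,
    oxygen and organic-carbon budget arithmetic for sediment incubations,
    negative-control-based contaminant OTU filtering with Bray-Curtis
    dissimilarities, and a synthetic-data module that simulates every
    input (Poisson ion counting, scan drift, bimodal enrichment,
    exponential regrowth, blank-enriched OTU tables) with known ground
    truth.
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
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    vegan,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
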