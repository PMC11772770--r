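Package: tipland
Title: Demand-Driven Land System Change Simulation with Adaptive
    Competitive Advantage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds 30-class land system rasters (ten land cover types by
    three within-cell density levels) from categorical land cover grids via
    majority upscaling and Jenks natural-breaks density classification,
    harmonizes integrated-assessment-model land area tables into per-basin
    demand for four land system services (cropland, forest, grassland,
    shrubland), fits random-forest location suitability surfaces from driver
    stacks, and runs a demand-driven cell allocation simulator in the
    CLUMondo family in which land systems supply several services at once and
    an adaptive competitive-advantage term steers iterative cell conversion
    until supply meets demand. Includes map-agreement validation (Cohen's
    kappa, figure of merit), a synthetic scene generator for controlled
    experiments, plain-text raster I/O, and a command line interface.
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
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
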