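Package: aqualeaf
Title: Aquaphotomics Analysis of Leaf Near-Infrared Spectra Under Drought Stress
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for aquaphotomics analysis of near-infrared
    (NIR) leaf spectra from drought experiments. Provides spectral data
    structures and CSV input/output, Savitzky-Golay derivative filtering and
    multiplicative scatter correction, aquagram computation over the 19 water
    matrix coordinates (WAMACs) of the first overtone region, Levene-gated
    Tukey/Dunnett-T3 significance tables for group comparisons, PLS1
    calibration of days of drought with leave-one-leaf-out cross-validation
    and SECV-based factor selection, and a synthetic spectra generator that
    emulates drought-dependent water-band dynamics for two genotypes with
    replicate structure, scatter and noise.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tibble,
    readr,
    dplyr,
    ggplot2,
    rlang,
    jsonlite,
    car
Suggests:
    testthat (>= 3.0.0),
    yaml,
    signal,
    optparse,
    withr
Config/testthat/edition: 3
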