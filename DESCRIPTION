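Package: rekar
Title: Quantification and Characterization of Red-Shifted FRET ERK Biosensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying genetically encoded FRET biosensors of ERK
    kinase activity from two-channel fluorescence intensities, with explicit
    correction for spectral crosstalk between near-infrared fluorophore pairs
    (miRFP670nano3/miRFP720, as in the REKAR sensors) as well as the classical
    two-filter CFP/YFP configuration (EKAREN4). Includes computation of
    calibration ratios from fluorophore, filter and light-source spectra; a
    seeded generator of synthetic single-cell activity time courses pushed
    through the forward optical model; the single-cell track filtering,
    smoothing, scaling and normalization pipeline; and per-cell dynamic range,
    noise-variance and signal-to-noise characterization with replicate-level
    one-way ANOVA and Tukey-Kramer multiple comparisons.
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
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml,
    zoo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
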