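Package: zoosonde
Title: Bi-Frequency Acoustic Estimation of Copepod Density and Biomass
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates large-copepod numerical density and dry-mass biomass from
    co-registered 38 and 120 kHz volume-backscatter grids. Implements dB-difference
    (delta-MVBS) classification of fish, krill and copepod echoes with a
    Gaussian-mixture fish gate, the high-pass fluid-sphere scattering model with
    monotone inversion from dB difference to equivalent spherical radius,
    Sv-minus-TS density inversion and echo integration to elementary sampling
    units, ZooScan-style area-to-dry-mass allometry, solar-altitude diel
    labelling, and ordinary kriging of areal biomass with total-biomass
    aggregation. Includes a seeded synthetic-survey generator that forward-models
    two-frequency echograms, net samples and plankton-scanner tables from known
    truth for closed-loop validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    jsonlite,
    yaml,
    geosphere
Suggests:
    testthat (>= 3.0.0),
    optparse,
    ape,
    mclust,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
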