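Package: lemnaquant
Title: Frond-Area Growth, Light-Use Efficiency and Photoprotection
    Analysis for Duckweed Dish Experiments
Version: 0.1.0
Authors@R:
    person("Duckweed", "Phenomics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantification pipeline for duckweed (Lemna gibba) grown in
    crystallizing dishes under a range of photosynthetic photon flux
    densities (PPFDs). Measures total frond area from top-down dish
    photographs by water-surface masking and HSV color thresholding,
    fits endpoint relative growth rates, integrates the photon dose
    received by an exponentially growing frond population and derives
    light-use efficiency, partitions absorbed excitation energy at
    photosystem II into photochemistry, thermal dissipation and excess
    from pulse-amplitude-modulated fluorescence yields, summarizes
    xanthophyll-cycle and other carotenoid pigment pools, and applies
    one-way ANOVA with Tukey-Kramer compact letter displays and simple
    linear regression. A seeded synthetic-data generator renders dish
    images with exact ground-truth frond masks and emits fluorescence
    and pigment tables with known parameters, so the whole pipeline is
    testable by parameter recovery without any raw instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    optparse,
    png,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
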