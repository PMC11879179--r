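Package: bftforage
Title: Visual Foraging, Bioenergetics and Food Limitation of Bluefin Tuna Larvae
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A mechanistic model of visual prey encounter, ingestion,
    metabolism and growth for Atlantic bluefin tuna (Thunnus thynnus)
    larvae in warm oligotrophic waters. Computes critical prey densities
    (maintenance and maximum-growth thresholds) for copepod nauplii,
    cladocerans and copepods across developmental stages (pre-flexion to
    post-flexion) and temperatures, assesses station-level food limitation
    in zooplankton survey tables, and generates synthetic survey stations
    with the statistical structure of Western Mediterranean ichthyoplankton
    cruises. The visual encounter kernel is calibrated in closed form from
    a single published threshold; all other thresholds are out-of-sample
    predictions.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
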