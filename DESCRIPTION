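Package: ccsa
Title: Carbon-Extended Consequence and Spatial Analysis for Fisheries Habitat Risk
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes Marine Stewardship Council style Consequence and Spatial
    Analysis (CSA) risk scores for benthic habitats exposed to towed
    bottom-contacting fishing gear, together with a blue-carbon extension that
    adds organic-carbon stock and accumulation productivity attributes and a
    quantitative swept-area-ratio (SAR) spatial attribute derived from gridded
    fishing-effort layers. Provides lookup-table attribute scorers, min-max
    carbon normalization with a precautionary dummy habitat, c-square grid
    processing and habitat overlap analysis on polygon maps, baseline versus
    carbon-mode comparison statistics, a saltmarsh-exclusion sensitivity
    analysis, a seeded synthetic-data generator (habitat mosaics, SAR fields,
    carbon tables), and a command-line front-end for reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
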