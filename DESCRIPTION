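Package: gasf
Title: Structure-Function Analysis of Geographic Atrophy from En-Face OCT
    Feature Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies geographic atrophy (GA) from per-feature OCT
    segmentation probability volumes and relates lesion topography to visual
    function. Segmentation probabilities for RPE-loss, photoreceptor
    degeneration and hypertransmission are reduced to en-face maps, RPE and
    outer retinal atrophy (RORA) is derived as per-A-scan co-occurrence, maps
    are standardised onto a fovea-centred ETDRS grid, and a bootstrapped
    random-forest regression predicts visual acuity under standard and low
    luminance from voxel-level feature probabilities. Normalised feature
    importance is aggregated per ETDRS subfield and rendered as en-face
    heatmaps. A synthetic-cohort simulator with a configurable
    structure-function law makes the full pipeline testable without access
    to clinical data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ranger,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
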