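Package: retmosaic
Title: Spatial Statistics and Simulation for Retinal Neuron Mosaics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the spatial organization of retinal cell
    mosaics and for testing the dendrite-soma exclusion model of mosaic
    formation. Implements edge-corrected density recovery profiles with
    Rodieck's effective radius, the Voronoi domain regularity index on
    window-clipped tessellations, hard-core and clustered point-process
    simulators with matched random-reference batteries, a resampling
    (unmatched-transposition) null for dendritic-territory soma enclosure
    with the enclosed cell index, flipped-image chance controls for
    dendrite-soma contact scoring, and clonal tangential-dispersion metrics.
    Includes seeded synthetic-mosaic generators that emulate regular,
    random, and aggregated soma arrays together with arbor territories,
    dendritic tip fields, and clone-column fields.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    car
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
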