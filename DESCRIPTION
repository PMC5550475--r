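Package: seedfate
Title: Seed Dispersal Effectiveness and Recruitment Success Under Defaunation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates the quantity and quality components of seed dispersal
    effectiveness for a large-seeded tree from field-style records (focal
    observations of fruiting trees, germination trials in randomized blocks,
    camera-trap surveys, dispersal-distance samples, and distance-dependent
    seed-survival experiments), combines them into an annual recruitment
    success via a pathway-wise seed-fate model, and simulates sequential
    seed-disperser loss with and without compensatory rewiring of seed
    removal under alternative seed-predator (escape-curve) scenarios.
    Includes a calibrated synthetic-data generator with known ground truth
    so the full pipeline can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
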