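Package: bwmetrics
Title: Structural Pattern Metrics from Black-and-White Images of Natural Structures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts digital photographs of natural structures (forest canopy,
    vertical vegetation profiles, bird-nest walls) into binary
    black/white/transparent matrices and computes structural pattern metrics:
    denseness (canopy closure) and openness, per-section black-pixel
    proportions, run-length ("hole") analysis of same-colour pixel sequences,
    light-gap edge distances, crest-height profiles and topline length,
    height quantiles of vertical denseness, a standardized pixel aggregation
    index based on same-colour-neighbour proportions with constructed
    extremal references, and square/circular matrix remapping for circular
    subjects. Includes deterministic synthetic image generators and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    png,
    EBImage,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
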