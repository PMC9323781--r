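Package: spheromap
Title: Seamless Surface Maps of Rotating Fruit from View Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a single longitude-by-latitude surface map of a piece of
    fruit from an ordered sequence of views captured while the fruit rotates
    under a fixed camera. The fruit is modelled as a spheroid (oblate,
    spherical or prolate); the 3D rotation between consecutive views is
    estimated from image texture alone, rotations are chained to propagate a
    fruit-centric axis frame to every view, and all views are fused into one
    seamless equirectangular map in which every pixel is drawn from at most
    two views with linear longitude blending. Includes area-weighted
    surface-fraction measurement on the map, a synthetic rotating-spheroid
    renderer that provides ground truth for every stage, and a small
    command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    grDevices,
    jsonlite,
    png,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
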