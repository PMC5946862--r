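Package: grooveprint
Title: Mapping DNA Minor Groove Width from Hydroxyl Radical Cleavage
    Electropherograms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Converts capillary-electrophoresis electropherograms of
    hydroxyl radical cleavage products of a DNA duplex into a
    nucleotide-resolution map of minor groove width (the experimental
    ORChID2 pattern). Provides Gaussian-mixture peak deconvolution with
    size-standard ladder assignment and three-pass sliding-window
    fitting, trapezoidal peak integration with median-window
    normalization, adenine calling from deuterium kinetic isotope
    effect trace pairs, cross-strand averaging and loess smoothing,
    a geometric minor groove width calculation from duplex coordinates,
    pentamer-table shape prediction, rank-correlation comparison of
    profiles over binding-site windows, and a synthetic
    electropherogram simulator with ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    pracma,
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    Biostrings,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
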