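Package: tuftmorph
Title: Morphometry of Tuft-Cell Cytoskeletal Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative image analysis of the tuft-cell cytoskeleton:
    nearest-neighbour and packing-angle statistics of filament cross-sections,
    Fourier-space detection and masking of lattice reflections with back-mapping
    of ordered filaments, 3D polymer tracing with pitch and actin-microtubule
    interaction (dilation-overlap) quantification, depth-resolved bundle and
    cell area, apical shape descriptors, and arclength intensity linescan
    model fitting (lognormal, four-parameter logistic, quartic, exponential
    decay). A seeded synthetic-data generator produces EM-like cross-section
    images, two-channel 3D network volumes and intensity profiles with known
    ground truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    tiff,
    minpack.lm,
    igraph,
    withr,
    EBImage,
    readr,
    stats,
    utils,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
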