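Package: oligouptake
Title: Quantification of Amyloid-Beta and Tau Oligomer Uptake into Neurons from Confocal Z-Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Mask-based colocalization analysis of fluorescently labeled
    protein oligomers (amyloid-beta, Tau) applied to cultured neurons and
    imaged as multichannel confocal Z-stacks. Binarizes a neuron-marker
    channel (MAP2-like) plane by plane, detects 3D fluorescent puncta in the
    oligomer channel, classifies each punctum as internalized or
    membrane-attached from its axial overlap with the neuron mask, and
    aggregates per-field uptake statistics including the internalization
    index (fraction of neurons internalizing times mean spots per neuron)
    with two-group comparisons. Ships a ground-truthed synthetic confocal
    scene generator so the whole pipeline is testable without raw microscopy
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    withr,
    xml2,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
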