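Package: rpeseg
Title: Self-Supervised Segmentation of Cell Borders in Flatmount Fluorescent Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains a convolutional encoder-decoder to segment closed cell-border
    networks (such as retinal pigment epithelium monolayers) in flatmount
    fluorescent microscopy patches without any manual labels. Training combines a
    Siamese stop-gradient pairwise representation loss on two corrupted views of
    each patch, an L1 reconstruction loss against the clean patch, and a morphology
    loss that pulls decoder outputs toward their own binarized closed-border maps.
    Corrupted view pairs are produced by a cut-and-paste augmentation family mixing
    a blur/noise/brightness branch with a bright-blob branch inside a random
    rectangle. Includes a Voronoi-tessellation synthetic patch generator with
    ground-truth border masks, the morphological binarization pipeline, dynamic
    loss-weight schedules, confusion-matrix segmentation metrics, and tiled
    whole-image inference.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
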