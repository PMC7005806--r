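Package: atlaswarp
Title: Region-Feature Diffeomorphic Registration and Block-Wise Warping
    of Large Brain Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Registration of whole-brain microscopy volumes to a reference
    atlas using manually delineated, anatomically conserved regional
    features instead of raw gray values. Provides a symmetric
    diffeomorphic optimizer that returns a linear matrix together with
    forward and inverse displacement fields at a coarse working
    resolution, and applies them to arbitrarily large full-resolution
    volumes block-by-block with on-the-fly trilinear interpolation of the
    deformation field. Also warps vectorized data (SWC neuron
    morphologies, point sets), generates 2D/3D synthetic validation
    models, and evaluates registration quality with multilevel Dice
    reports, STAPLE consensus fusion and Mann-Whitney statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    parallel,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
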