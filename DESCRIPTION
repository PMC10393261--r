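Package: SynapseMorph
Title: Microtubule Radiality and Morphometry of the Immunological Synapse
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantitative image analysis of T-cell immunological synapses
    from single-channel fluorescence microscopy. Implements the
    Degree-of-Radiality (DoR) statistic for microtubule network
    organization (Otsu segmentation, convex-hull radial/circular vector
    fields, structure-tensor orientation estimation, elliptical Fourier
    contour interpolation into radial sections), per-cell shape metrics
    (Crofton perimeter, convex-hull roughness, moment-ellipse roundness),
    centrosome-polarization distance binning, and F-actin line-intensity
    profiles. A seeded synthetic-image generator with analytic ground
    truth supports validation, and two-group per-cell statistics
    (Student's t, Mann-Whitney) with box-plot reporting complete the
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    grDevices,
    utils,
    tiff,
    yaml,
    igraph,
    pracma,
    EBImage,
    ggplot2,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: CellBiology, Immunooncology, Visualization
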