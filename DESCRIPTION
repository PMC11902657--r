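Package: orchardsar
Title: Near-Field Millimeter-Wave SAR Imaging and Apple Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates near-field planar-aperture millimeter-wave synthetic
    aperture radar (SAR) echoes from point-scatterer orchard scenes,
    reconstructs 3D reflectivity volumes with a wavenumber-domain
    range-migration algorithm (Stolt interpolation), and detects apple
    targets in the resulting speckle imagery with a compact convolutional
    detector built around dynamic spatial pyramid pooling, recursive
    multi-scale feature fusion, and non-local context enhancement. Includes
    a synthetic orchard dataset generator, COCO-style annotation I/O,
    focal-loss training, and AP/Recall/F1 evaluation at IoU 0.5, so the
    whole pipeline runs at desk scale on a single CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
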