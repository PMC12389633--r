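Package: plantrcnn
Title: Lightweight Two-Stage Plant Detection with Spatial Attention and
    Unsharp-Mask Enhancement
Version: 0.1.0
Authors@R:
    person("plantrcnn", "developers", email = "plantrcnn@example.org",
           role = c("aut", "cre"))
Description: A desk-scale toolkit for wild-plant object detection built
    around a lightweight two-stage detector: unsharp-masking image
    enhancement, a grouped spatial-attention operator gated by channel-wise
    max/average pooling, a depthwise-separable bottleneck backbone in a
    ResNet-50 layout, a region proposal network with RoI max pooling,
    Pascal VOC annotation I/O with stratified splitting, VOC-style
    detection metrics (precision, recall, F1, AP, mAP), a synthetic
    plant-scene generator so every component is testable without external
    data, and a model-complexity profiler with an edge-performance
    scaling model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    xml2,
    yaml,
    jsonlite,
    png,
    jpeg,
    stats,
    grDevices,
    graphics,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
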