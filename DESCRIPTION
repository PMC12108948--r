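Package: bwseg
Title: Rotation-Aware Single-Tooth Segmentation of Bitewing Radiographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Segments individual teeth (and half-teeth) from bitewing dental
    radiographs using a projection-profile method that first recovers the
    image's rotation by a coarse-to-fine search over the masked horizontal
    projection of the binarized image, then splits the corrected image into
    upper and lower jaws at the occlusal trough and into single teeth at
    vertical-projection valleys. Ships a contrast-enhancement operator bank
    (intensity value mapping, global histogram equalization, contrast-limited
    adaptive histogram equalization and their ordered combinations), detection
    evaluation statistics (confusion-matrix metrics, box IoU, average
    precision, mAP, a paired t-test on IoU values), and a deterministic
    synthetic bitewing phantom generator with exact ground truth so the whole
    pipeline is testable without clinical data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    tiff,
    png
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
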