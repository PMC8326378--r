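Package: aortrack
Title: Multi-Task Keypoint Tracking for TAVI Aortography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tracking of aortic-root and delivery-system landmarks on
    intraoperative aortography frames during transcatheter aortic valve
    implantation (TAVI). Implements an 11-keypoint annotation schema, a
    hard-parameter-sharing convolutional model with a multi-label
    classification head and a coordinate-regression head, the weighted
    binary cross-entropy + log-cosh composite loss with masking of absent
    keypoints, micro/macro classification metrics and masked regression
    errors, Rectified Adam training with early stopping, annulus-plane
    guidance geometry with pigtail binding for contrast-free frames, and a
    synthetic fluoroscopy phantom generator so the whole pipeline runs
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    png,
    yaml,
    Matrix,
    EBImage,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
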