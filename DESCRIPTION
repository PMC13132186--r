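Package: primatrack
Title: Multi-Animal Tracking, Identification and Evaluation for Primate Videos
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multi-animal tracking in videos of nonhuman primates:
    decoding of center-point detector head outputs into detections, two-stage
    data association combining a constant-velocity Kalman filter with
    appearance embeddings via Hungarian assignment, primate-adapted track
    lifecycle rules (lowered detection threshold, new-track overlap
    suppression, image-border filtering, second-stage association at the last
    detection), copy-paste synthesis of detection training data from masked
    instance cutouts, track-level individual identification by exponentially
    weighted confidence voting, and a full evaluation suite (HOTA, MOTA, IDF1,
    COCO-style mAP/AP50, box-versus-keypoint detection comparison, annotation
    consistency). A seeded scene simulator generates ground-truth tracks with
    jump and occlusion events, noisy detections with identity-informative
    embeddings, and rendered frames, so every component is testable without
    trained network weights or field video data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
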