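Package: fatiguemap
Title: Quantifying Visitor Fatigue from Skeletal Keypoint Streams
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Contact-free quantification of museum visitor fatigue from 2-D human
    pose estimation output. Reads per-frame COCO-17 keypoint streams, classifies
    three compensatory postures (squatting, hands-on-hips, single-leg raise) by
    explicit geometric rules, confirms posture states over consecutive frames,
    accumulates a weighted normalized per-visitor fatigue score, and aggregates
    per-spatial-unit Fatigue Indices with band classification, heatmap export and
    pre/post-intervention comparison. Also provides occlusion-aware camera
    coverage metrics with a greedy/exhaustive placement planner, frame-quality
    metrics (Laplacian variance, Sobel gradient measures, RMS contrast, color-cast
    index) with a risk-gated routing interface for external image enhancers, and a
    synthetic generator of keypoint tracks, visitor populations, floor plans and
    test images with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: jsonlite, png, stats, utils, grDevices, graphics
Suggests: testthat (>= 3.0.0), mgcv
Config/testthat/edition: 3
RoxygenNote: 7.3.3
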