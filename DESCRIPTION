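Package: heatfuse
Title: Wildlife Detection in Aerial Thermal Video by Detector Fusion and
    Temporal Heat-Map Accumulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects warm-bodied wildlife (koalas and similar arboreal
    mammals) in low-altitude aerial thermal video by fusing the bounding-box
    output of multiple object detectors into binary heat maps, registering
    consecutive frames with keypoint homographies, accumulating evidence
    with an exponential moving average, extracting size-gated candidate
    signatures by connected-component analysis, tracking them greedily
    across frames, georeferencing tracked events, and scoring surveys
    against ground-truth animal positions (probability of detection,
    precision rate, RMSE, MAE). Includes a synthetic thermal survey
    simulator with mock noisy detectors so the full pipeline can be
    exercised and validated without trained neural networks or field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
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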