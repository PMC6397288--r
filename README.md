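# heatfuse

Automated detection of warm-bodied wildlife — koalas and similar cryptic,
canopy-dwelling mammals — in low-altitude aerial thermal video, and the
survey-evaluation framework that goes with it.

Single-frame object detectors miss animals (canopy occlusion, sensor
noise) and fire on transient clutter. `heatfuse` implements the pipeline
that mitigates both: the bounding-box output of several detectors is
rasterized into binary *heat maps*, averaged across detectors, aligned
frame-to-frame with keypoint homographies, and pooled over time with the
registered exponential moving average

```
A(t) = I(t)/N + ((N-1)/N) · A(t-1),
```

with a reset `A(t) = I(t)` whenever registration fails (fewer than 4
point matches). Connected regions of the accumulated map with evidence
≥ 0.05 and both dimensions in 3–30 px become candidate signatures; a
greedy motion-compensated tracker collapses them to one event per animal;
events are georeferenced with a nadir camera model, classified
(candidate / kangaroo / car / human / other) and matched one-to-one to
ground-surveyed animal positions. Surveys are scored by probability of
detection `Pd = K_detected / K_obs`, precision rate
`PR = K_detected / (K_obs + K_false)`, and across surveys by RMSE and MAE
of the count error.

Because trained neural detectors and field imagery are out of scope, the
package includes a deterministic synthetic survey simulator (thermal
frames, ground truth, telemetry, exact homographies, noisy mock
detectors) so the entire pipeline is testable end-to-end, plus a bundled
table of eleven real koala surveys (Petrie, Queensland) for the
evaluation arithmetic.

## Worked example

```r
library(heatfuse)

scene <- scene_config(seed = 11, extent_m = c(46, 100), n_animals = 5,
                      frame_shape = c(192, 256), gsd = 0.18,
                      sensor_noise_sd = 150)
survey <- generate_survey(scene)
survey
#> thermal survey 'sim': 74 frames 192x256 px, 6 objects (5 animal, 1 kangaroo)

dets <- rbind(
  run_mock_detector(survey, detector_noise("det_a", miss_rate = 0.3,
                                           fp_rate = 0.2, seed = 5)),
  run_mock_detector(survey, detector_noise("det_b", miss_rate = 0.3,
                                           fp_rate = 0.2, seed = 6)))
res <- run_survey_pipeline(survey, dets, pipeline_config())
summary(res)
#> wildlife detections: survey 'sim'
#>   animals present 5 | detected 5 | false ('other') 1
#>   Pd = 100%, PR = 83%
#>   events by label: kangaroo=0 car=0 human=0 other=1
#>   frames 74 | accumulator resets 0 | mean candidates/frame 1.50
#>   mean registration reprojection error 1.281 px
```

Despite each mock detector missing 30% of the visible animals per frame,
the accumulated evidence keeps every persistent animal above the
candidate threshold: all 5 animals are recovered (Pd 100%), and one
spurious track survives as an `other` signature (PR 83% = 5/(5+1)).

The evaluation framework on the bundled testing-survey counts:

```r
pc <- subset(petrie_survey_counts(), role == "testing")
survey_report(rbind(
  data.frame(survey_id = pc$survey_id, method = "automated",
             k_obs = pc$k_obs, k_detected = pc$k_auto),
  data.frame(survey_id = pc$survey_id, method = "manual",
             k_obs = pc$k_obs, k_detected = pc$k_manual)))
#> Survey detection report
#>  survey_id    method k_obs k_detected k_false pd_pct pr_pct
#>    North 4 automated    15         14      NA     93     NA
#>    North 5 automated    18         17      NA     94     NA
#>    North 6 automated    19         15      NA     79     NA
#>    South 3 automated     9          7      NA     78     NA
#>    South 4 automated    11          9      NA     82     NA
#>    South 5 automated     6          6      NA    100     NA
#>   (pooled) automated    78         68      NA     87     NA
#>    ...
#>   (pooled)    manual    78         49      NA     63     NA
```

The automated method pools to 87% probability of detection on the
testing surveys against 63% for manual review of the same footage.

## Command line

A thin wrapper over the same functions ships with the package:

```sh
CLI=$(Rscript -e 'cat(system.file("scripts", "heatfuse", package = "heatfuse"))')
Rscript "$CLI" simulate --out fixture --seed 7 --animals 4 \
    --extent-east 46 --extent-north 100 --gsd 0.18 --height 192 --width 256
Rscript "$CLI" fuse --fixture fixture --out results
Rscript "$CLI" evaluate --counts counts.csv --out report
```

`simulate` writes a fixture directory (16-bit TIFF frames, CSV
telemetry/truth, YAML manifest, two mock-detector files); `fuse` runs the
pipeline and writes events as CSV and GeoJSON with diagnostics;
`evaluate` renders a survey report from a
`survey_id,method,k_obs,k_detected,k_false` counts file. Identical
config and seed give byte-identical outputs.

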