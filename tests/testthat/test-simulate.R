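test_that("an empty scene renders background only, deterministically", {
  cfg <- scene_config(seed = 2, extent_m = c(40, 40), n_animals = 0,
                      n_kangaroos = 0, frame_shape = c(96, 128),
                      gsd = 0.2, n_frames = 4, sensor_noise_sd = 0)
  sv <- generate_survey(cfg)
  expect_equal(nrow(sv$truth), 0)
  expect_equal(nrow(sv$objects), 0)
  expect_equal(length(sv$frames), 4)
  ## background stays within the texture's plausible range (no warm blobs)
  expect_lt(max(sv$frames[[1]]), cfg$bg_mean + 8 * cfg$bg_sd)
  sv2 <- generate_survey(cfg)
  expect_identical(sv$frames, sv2$frames)
  expect_identical(sv$truth, sv2$truth)
  expect_error(scene_config(extent_m = c(-5, 10)), "extent")
  expect_error(scene_config(occlusion_prob = 1.4), "rates")
})

test_that("per-frame camera translation matches survey kinematics", {
  cfg <- small_scene(seed = 5, n_animals = 0, n_kangaroos = 0,
                     n_frames = 6, sensor_noise_sd = 0)
  sv <- generate_survey(cfg)
  expected <- (cfg$speed_ms / cfg$frame_rate_hz) / cfg$gsd
  for (t in 2:6) {
    h <- sv$homographies[[t]]
    expect_equal(sqrt(h[1, 3]^2 + h[2, 3]^2), expected, tolerance = 1e-9)
    expect_equal(h[1, 1], 1)                 # pure translation, no rotation
  }
})

test_that("the returned homography aligns consecutive frames to subpixel error", {
  cfg <- small_scene(seed = 19, n_animals = 0, n_kangaroos = 0,
                     n_frames = 3, sensor_noise_sd = 0)
  sv <- generate_survey(cfg)
  f1 <- sv$frames[[1]] / 65535; f2 <- sv$frames[[2]] / 65535
  warped <- warp_heatmap(f1, sv$homographies[[2]])
  inner_r <- 30:160; inner_c <- 30:220
  mae_aligned <- mean(abs(warped[inner_r, inner_c] - f2[inner_r, inner_c]))
  mae_raw <- mean(abs(f1[inner_r, inner_c] - f2[inner_r, inner_c]))
  expect_lt(mae_aligned, 0.3 * mae_raw)
})

test_that("kangaroo-scale distractors are wide and fast relative to animals", {
  cfg <- small_scene(seed = 29, n_animals = 4, n_kangaroos = 2,
                     n_frames = 40)
  sv <- generate_survey(cfg)
  kang <- sv$truth[sv$truth$class == "kangaroo", ]
  expect_true(all(kang$x1 - kang$x0 > 20))
  ## per-frame ground displacement: animals static, kangaroos moving
  ko <- sv$objects[sv$objects$class == "kangaroo", ]
  kang_disp <- sqrt(ko$ve^2 + ko$vn^2) / cfg$frame_rate_hz / cfg$gsd
  expect_true(all(kang_disp > 0.5))
  an <- sv$objects[sv$objects$class == "animal", ]
  expect_true(all(sqrt(an$ve^2 + an$vn^2) == 0))
})

test_that("mock detector noise model honours its contract", {
  cfg <- small_scene(seed = 3, n_animals = 12, n_kangaroos = 0,
                     extent_m = c(46, 125))
  sv <- generate_survey(cfg)
  none <- run_mock_detector(sv, detector_noise(miss_rate = 1, fp_rate = 0,
                                               seed = 1))
  expect_equal(nrow(none), 0)

  exact <- run_mock_detector(sv, detector_noise(miss_rate = 0, fp_rate = 0,
                                                jitter_px = 0, seed = 1))
  vis <- sv$truth[sv$truth$visible, ]
  expect_equal(nrow(exact), nrow(vis))
  expect_equal(exact[, c("x0", "y0", "x1", "y1")],
               vis[, c("x0", "y0", "x1", "y1")], ignore_attr = TRUE)

  ## miss rate 0.3: detections within 3 binomial sd of 0.7 * n
  n_vis <- nrow(vis)
  expect_gt(n_vis, 250)
  d30 <- run_mock_detector(sv, detector_noise(miss_rate = 0.3, fp_rate = 0,
                                              seed = 8))
  expected <- 0.7 * n_vis
  sd3 <- 3 * sqrt(n_vis * 0.3 * 0.7)
  expect_gt(nrow(d30), expected - sd3)
  expect_lt(nrow(d30), expected + sd3)
  ## determinism
  d30b <- run_mock_detector(sv, detector_noise(miss_rate = 0.3, fp_rate = 0,
                                               seed = 8))
  expect_identical(d30, d30b)
})

test_that("fixtures round-trip exactly through disk", {
  cfg <- small_scene(seed = 14, n_animals = 2, n_kangaroos = 1,
                     n_frames = 10)
  sv <- generate_survey(cfg)
  dir <- file.path(tempdir(), "fix_roundtrip")
  unlink(dir, recursive = TRUE)
  mf <- write_fixture(sv, dir)
  expect_equal(mf$n_frames, 10)
  back <- read_fixture(dir)
  expect_identical(back$frames, sv$frames)
  expect_equal(back$truth, sv$truth, ignore_attr = TRUE)
  expect_equal(back$telemetry, sv$telemetry, ignore_attr = TRUE)
  expect_equal(back$terrain, sv$terrain)
  for (t in 2:10)
    expect_equal(unclass(back$homographies[[t]]),
                 unclass(sv$homographies[[t]]), ignore_attr = TRUE)

  ## empty scene: manifest carries zero truth rows
  sv0 <- generate_survey(scene_config(seed = 1, extent_m = c(30, 30),
                                      n_animals = 0, n_kangaroos = 0,
                                      frame_shape = c(64, 64), gsd = 0.3,
                                      n_frames = 3))
  dir0 <- file.path(tempdir(), "fix_empty")
  unlink(dir0, recursive = TRUE)
  write_fixture(sv0, dir0)
  expect_equal(nrow(read_fixture(dir0)$truth), 0)
})
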