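cam8 <- camera_model(gsd = 0.08)

test_that("nadir projection: principal point, scaled offsets, heading rotation", {
  shape <- c(512, 640)
  cx <- (640 - 1) / 2; cy <- (512 - 1) / 2
  g <- pixel_to_ground(cx, cy, east = 100, north = 200, heading_deg = 37,
                       shape = shape, camera = cam8)
  expect_equal(as.numeric(g), c(100, 200))

  g2 <- pixel_to_ground(cx + 100, cy, 0, 0, 0, shape, cam8)
  expect_equal(as.numeric(g2), c(8, 0))

  ## heading 90 (east): the (right, forward) = (8, 4) m offset rotates so
  ## forward maps to east and right maps to south
  g3 <- pixel_to_ground(cx + 100, cy - 50, 0, 0, 90, shape, cam8)
  th <- 90 * pi / 180
  expected_e <- 8 * cos(th) + 4 * sin(th)
  expected_n <- -8 * sin(th) + 4 * cos(th)
  expect_equal(as.numeric(g3), c(expected_e, expected_n))
  expect_equal(as.numeric(g3), c(4, -8), tolerance = 1e-12)
})

test_that("ground-to-pixel inverts pixel-to-ground to 1e-6 px", {
  set.seed(6)
  shape <- c(200, 300)
  for (rep in 1:20) {
    px <- runif(1, 0, 299); py <- runif(1, 0, 199)
    e0 <- runif(1, -50, 50); n0 <- runif(1, -50, 50)
    hd <- runif(1, 0, 360)
    g <- pixel_to_ground(px, py, e0, n0, hd, shape, cam8)
    p <- ground_to_pixel(g[, "east"], g[, "north"], e0, n0, hd, shape, cam8)
    expect_lt(abs(p[, "px"] - px), 1e-6)
    expect_lt(abs(p[, "py"] - py), 1e-6)
  }
})

test_that("signature classification follows the rule cascade", {
  ev <- data.frame(mean_w = c(25, 8, 8, 45, 10),
                   mean_h = c(22, 8, 8, 20, 10),
                   disp_px_per_frame = c(6, 0.3, 6, 2, 2),
                   east = c(50, 10, 10, 50, 50), north = 10)
  terrain <- heatfuse:::terrain_open_east(40)
  lab <- classify_events(ev, terrain)
  expect_equal(lab, c("kangaroo", "candidate", "other", "car", "human"))
  ## without a terrain mask the terrain rules are skipped
  expect_message(lab2 <- classify_events(ev, NULL), "terrain")
  expect_equal(lab2, c("other", "candidate", "other", "other", "other"))
})

test_that("ground-truth matching is one-to-one, greedy and radius-gated", {
  animals <- data.frame(animal_id = c("a1", "a2"),
                        east = c(0, 100), north = c(0, 0))
  ## zero events: everything undetected
  ev0 <- data.frame(east = numeric(), north = numeric(),
                    label = character())
  m0 <- match_to_ground_truth(ev0, animals)
  expect_equal(sort(m0$undetected_animals), c("a1", "a2"))

  ev1 <- data.frame(east = 3, north = 4, label = "candidate")
  m1 <- match_to_ground_truth(ev1, animals, radius_m = 15)
  expect_equal(m1$events$matched_animal, "a1")
  expect_equal(m1$matches$dist_m, 5)

  ## two events near one animal: one matches, the other becomes 'other'
  ev2 <- data.frame(east = c(1, 2), north = c(0, 0),
                    label = c("candidate", "candidate"))
  m2 <- match_to_ground_truth(ev2, animals, radius_m = 15)
  expect_equal(sum(!is.na(m2$events$matched_animal)), 1)
  expect_equal(m2$events$matched_animal[1], "a1")  # nearer event wins
  expect_equal(m2$events$label[2], "other")
  expect_equal(m2$undetected_animals, "a2")
})

test_that("matched count is monotone in the matching radius", {
  set.seed(9)
  animals <- data.frame(animal_id = paste0("a", 1:6),
                        east = runif(6, 0, 100), north = runif(6, 0, 100))
  ev <- data.frame(east = animals$east + rnorm(6, sd = 8),
                   north = animals$north + rnorm(6, sd = 8),
                   label = "candidate")
  n_prev <- -1
  for (r in c(2, 5, 10, 20, 40)) {
    n <- nrow(match_to_ground_truth(ev, animals, radius_m = r)$matches)
    expect_gte(n, n_prev)
    n_prev <- n
  }
})

test_that("simulated static animals georeference to within one pixel on the ground", {
  cfg <- small_scene(seed = 11, n_animals = 5, n_kangaroos = 0,
                     n_frames = 55)
  sv <- generate_survey(cfg)
  d1 <- run_mock_detector(sv, detector_noise("a", miss_rate = 0, fp_rate = 0,
                                             jitter_px = 0, seed = 5))
  res <- run_survey_pipeline(sv, d1, pipeline_config(registration = "truth"))
  expect_gt(nrow(res$matches), 0)
  expect_lt(max(res$matches$dist_m), 1.5 * cfg$gsd)
})
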