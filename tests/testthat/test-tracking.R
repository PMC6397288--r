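cand_df <- function(cx, cy, w = 5, h = 5, heat = 0.5) {
  data.frame(cand_id = seq_along(cx), cx = cx, cy = cy,
             x0 = cx - w / 2, y0 = cy - h / 2, x1 = cx + w / 2,
             y1 = cy + h / 2, w = w, h = h, n_px = w * h, mean_heat = heat)
}

test_that("candidates with no active tracks spawn one track each", {
  tk <- heatfuse:::new_tracker()
  tk <- associate_step(tk, cand_df(c(5, 20, 40), c(5, 20, 40)), frame = 0)
  expect_equal(length(tk$tracks), 3)
  expect_equal(vapply(tk$tracks, function(t) t$id, integer(1)), 1:3)
})

test_that("greedy gating extends near tracks and spawns far candidates", {
  tk <- heatfuse:::new_tracker(gate_px = 5)
  tk <- associate_step(tk, cand_df(10, 10), frame = 0)
  tk <- associate_step(tk, cand_df(c(11, 30), c(10, 30)), frame = 1)
  expect_equal(length(tk$tracks), 2)
  expect_equal(nrow(tk$tracks[[1]]$members), 2)
  expect_equal(tk$tracks[[1]]$members$cx[2], 11)
  expect_equal(nrow(tk$tracks[[2]]$members), 1)
})

test_that("an equidistant candidate joins the lower track id", {
  tk <- heatfuse:::new_tracker(gate_px = 10)
  tk <- associate_step(tk, cand_df(c(10, 20), c(10, 10)), frame = 0)
  tk <- associate_step(tk, cand_df(15, 10), frame = 1)
  expect_equal(nrow(tk$tracks[[1]]$members), 2)
  expect_equal(nrow(tk$tracks[[2]]$members), 1)
})

test_that("no candidate is ever assigned to two tracks", {
  set.seed(41)
  tk <- heatfuse:::new_tracker(gate_px = 12)
  for (t in 0:10) {
    n <- sample(1:6, 1)
    tk <- associate_step(tk, cand_df(runif(n, 0, 50), runif(n, 0, 50)),
                         frame = t)
    frames_used <- lapply(tk$tracks, function(tr) tr$members$frame)
    for (tr in tk$tracks)
      expect_false(any(duplicated(tr$members$frame)))
    ## candidates at frame t across tracks are distinct rows
    at_t <- do.call(rbind, lapply(tk$tracks, function(tr)
      tr$members[tr$members$frame == t, c("cx", "cy")]))
    if (!is.null(at_t) && nrow(at_t) > 1)
      expect_false(any(duplicated(at_t)))
  }
})

test_that("greedy association matches the naive greedy oracle", {
  set.seed(17)
  for (rep in 1:15) {
    n_tr <- sample(2:4, 1); n_cd <- sample(2:4, 1)
    tpos <- cbind(runif(n_tr, 0, 40), runif(n_tr, 0, 40))
    cpos <- cbind(runif(n_cd, 0, 40), runif(n_cd, 0, 40))
    gate <- 25
    tk <- heatfuse:::new_tracker(gate_px = gate, max_missed = 99)
    tk <- associate_step(tk, cand_df(tpos[, 1], tpos[, 2]), frame = 0)
    tk <- associate_step(tk, cand_df(cpos[, 1], cpos[, 2]), frame = 1)
    D <- sqrt(outer(tpos[, 1], cpos[, 1], "-")^2 +
                outer(tpos[, 2], cpos[, 2], "-")^2)
    ref <- greedy_assignment_oracle(D, seq_len(n_tr), gate)
    got <- do.call(rbind, lapply(seq_len(n_tr), function(i) {
      m <- tk$tracks[[i]]$members
      if (nrow(m) == 2) c(i, which(cpos[, 1] == m$cx[2] &
                                     cpos[, 2] == m$cy[2])) else NULL
    }))
    ref_m <- do.call(rbind, ref)
    if (is.null(ref_m)) expect_null(got) else {
      expect_equal(got[order(got[, 1]), , drop = FALSE],
                   ref_m[order(ref_m[, 1]), , drop = FALSE],
                   ignore_attr = TRUE)
    }
  }
})

test_that("greedy equals the optimal assignment on well-separated instances", {
  ## each candidate lies near exactly one track, far from all others: the
  ## brute-force minimum-cost assignment and greedy must coincide
  set.seed(23)
  for (rep in 1:10) {
    n <- sample(2:4, 1)
    centers <- cbind(seq(0, by = 100, length.out = n), 0)
    jitter <- matrix(runif(2 * n, -3, 3), n, 2)
    tpos <- centers; cpos <- centers + jitter
    gate <- 10
    D <- sqrt(outer(tpos[, 1], cpos[, 1], "-")^2 +
                outer(tpos[, 2], cpos[, 2], "-")^2)
    opt <- optimal_assignment_oracle(D, gate)
    tk <- heatfuse:::new_tracker(gate_px = gate, max_missed = 99)
    tk <- associate_step(tk, cand_df(tpos[, 1], tpos[, 2]), frame = 0)
    tk <- associate_step(tk, cand_df(cpos[, 1], cpos[, 2]), frame = 1)
    got <- do.call(rbind, lapply(seq_len(n), function(i) {
      m <- tk$tracks[[i]]$members
      if (nrow(m) == 2) c(i, which(cpos[, 1] == m$cx[2])) else NULL
    }))
    expect_equal(got[order(got[, 1]), , drop = FALSE],
                 opt[order(opt[, 1]), , drop = FALSE], ignore_attr = TRUE)
  }
})

test_that("track motion compensation uses the supplied homography", {
  tk <- heatfuse:::new_tracker(gate_px = 4)
  tk <- associate_step(tk, cand_df(10, 10), frame = 0)
  ## camera moved: the same object appears 8 px down; gate alone (4 px)
  ## would miss, but compensation warps the track into the new frame
  tk <- associate_step(tk, cand_df(10, 18), frame = 1,
                       h = homography_translation(0, 8))
  expect_equal(length(tk$tracks), 1)
  expect_equal(nrow(tk$tracks[[1]]$members), 2)
  expect_equal(tk$tracks[[1]]$disp_sum, 0)    # fully compensated
})

test_that("events require the minimum length and report one event per animal", {
  tk <- heatfuse:::new_tracker()
  tk <- associate_step(tk, cand_df(c(10, 30), c(10, 30)), frame = 0)
  tk <- associate_step(tk, cand_df(10, 10), frame = 1)  # only track 1 continues
  for (t in 2:9) tk <- associate_step(tk, cand_df(10, 10), frame = t)
  tk <- heatfuse:::close_all_tracks(tk)
  ev <- finalize_events(tk, min_length = 2)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$length, 10)
  ev0 <- finalize_events(tk, min_length = 11)
  expect_equal(nrow(ev0), 0)
})

test_that("a noise-free simulated survey yields one event per visible animal", {
  cfg <- small_scene(seed = 11, n_animals = 5, n_kangaroos = 0,
                     n_frames = 55)
  sv <- generate_survey(cfg)
  d1 <- run_mock_detector(sv, detector_noise("a", miss_rate = 0, fp_rate = 0,
                                             jitter_px = 0, seed = 5))
  d2 <- run_mock_detector(sv, detector_noise("b", miss_rate = 0, fp_rate = 0,
                                             jitter_px = 0, seed = 6))
  res <- run_survey_pipeline(sv, rbind(d1, d2),
                             pipeline_config(registration = "truth"))
  animals <- unique(sv$objects$object_id[sv$objects$class == "animal"])
  n_visible <- sum(vapply(animals, function(a)
    max_visible_run(sv$truth, a) >= 2, logical(1)))
  expect_equal(nrow(res$events), n_visible)
  expect_equal(sum(!is.na(res$events$matched_animal)), n_visible)
  expect_false(any(duplicated(stats::na.omit(res$events$matched_animal))))
})
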