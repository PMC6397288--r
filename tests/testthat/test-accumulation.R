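ident_reg <- function() heatfuse:::registration_from_homography(
  homography_identity())

test_that("combining heat maps averages pixel-wise", {
  a <- matrix(0, 8, 8); a[2:4, 2:4] <- 1
  expect_equal(combine_heatmaps(list(a, a)), a)
  z <- matrix(0, 8, 8)
  comb <- combine_heatmaps(list(a, z))
  expect_equal(comb[3, 3], 0.5)
  expect_equal(comb[7, 7], 0)
  expect_true(all(comb %in% c(0, 0.5)))
  expect_equal(combine_heatmaps(list(a)), a)
  expect_error(combine_heatmaps(list(a, matrix(0, 4, 4))), "shape")
})

test_that("accumulator follows the closed form under constant input", {
  ## A(k) = v (1 - ((N-1)/N)^k) from A(0) = 0 — oracle: iterate the
  ## recurrence directly and compare both to the closed form
  for (N in c(3, 9)) {
    v <- 0.8
    st <- accumulator_init(matrix(0, 6, 6), N = N)
    a_scalar <- 0
    for (k in 1:12) {
      st <- update_accumulator(st, matrix(v, 6, 6), ident_reg())
      a_scalar <- v / N + (N - 1) / N * a_scalar
      expect_equal(st$A[3, 3], v * (1 - ((N - 1) / N)^k),
                   tolerance = 1e-12)
      expect_equal(st$A[3, 3], a_scalar, tolerance = 1e-14)
    }
  }
})

test_that("registration failure resets the accumulator to A(t) = I(t)", {
  st <- accumulator_init(matrix(0.7, 6, 6), N = 9)
  I_t <- matrix(runif(36), 6, 6)
  st2 <- update_accumulator(st, I_t, reg = NULL)
  expect_identical(st2$A, I_t)
  expect_equal(st2$resets, 1L)
  failed <- structure(list(homography = NULL, num_matches = 2L,
                           reproj_err = NA_real_),
                      class = "registration_result")
  st3 <- update_accumulator(st2, matrix(0.1, 6, 6), failed)
  expect_equal(st3$A, matrix(0.1, 6, 6))
  expect_equal(st3$resets, 2L)
})

test_that("N = 1 collapses the recurrence to A(t) = I(t)", {
  st <- accumulator_init(matrix(0.9, 6, 6), N = 1)
  I_t <- matrix(runif(36), 6, 6)
  st <- update_accumulator(st, I_t, ident_reg())
  expect_equal(st$A, I_t)
  expect_error(accumulator_init(matrix(0, 2, 2), N = 0), "N")
})

test_that("A(t-1) is a fixed point when I(t) equals it under identity motion", {
  A0 <- matrix(runif(64), 8, 8)
  st <- accumulator_init(A0, N = 9)
  st <- update_accumulator(st, A0, ident_reg())
  expect_equal(st$A, A0)
})

test_that("accumulator values stay within [0, 1] for arbitrary inputs", {
  set.seed(12)
  st <- accumulator_init(matrix(runif(64), 8, 8), N = 4)
  for (k in 1:20) {
    h <- homography_similarity(dx = runif(1, -2, 2), dy = runif(1, -2, 2),
                               theta_deg = runif(1, -2, 2), center = c(4, 4))
    st <- update_accumulator(st, matrix(runif(64), 8, 8),
                             heatfuse:::registration_from_homography(h))
    expect_true(all(st$A >= 0 & st$A <= 1))
  }
})

test_that("fusion streaming: empty detections, single frames, monotone growth", {
  shape <- c(16, 16)
  ed <- heatfuse:::empty_detections()
  fr <- run_fusion(ed, shape, frame_indices = 0:4, keep_maps = TRUE)
  expect_true(all(vapply(fr$maps, max, numeric(1)) == 0))

  one <- data.frame(survey_id = "s", frame = 0L, detector_id = c("a", "b"),
                    label = "koala", x0 = 4, y0 = 4, x1 = 9, y1 = 9,
                    confidence = 0.9)
  fr1 <- run_fusion(one, shape, frame_indices = 0L, keep_maps = TRUE)
  expect_equal(fr1$maps[[1]], rasterize_boxes(one, shape))

  ## a detection appearing at frame 5 and persisting on a static camera:
  ## evidence under the box grows monotonically toward 1
  persistent <- do.call(rbind, lapply(5:24, function(t)
    transform(one, frame = t)))
  fr2 <- run_fusion(persistent, shape, frame_indices = 0:24, N = 9,
                    keep_maps = TRUE)
  vals <- vapply(fr2$maps, function(m) m[6, 6], numeric(1))
  expect_true(all(vals[1:5] == 0))
  expect_true(all(diff(vals[6:25]) > 0))
  expect_gt(vals[25], 0.85)
  expect_lt(max(vals), 1 + 1e-12)
})

test_that("accumulation keeps persistent animals above threshold despite 30% misses", {
  ## static camera, two detectors each missing 30% of frames independently
  set.seed(77)
  shape <- c(16, 16)
  n_fr <- 120; N <- 9
  rows <- list()
  for (t in 0:(n_fr - 1)) for (d in c("a", "b")) {
    if (runif(1) < 0.3) next
    rows[[length(rows) + 1L]] <- data.frame(
      survey_id = "s", frame = t, detector_id = d, label = "koala",
      x0 = 5, y0 = 5, x1 = 10, y1 = 10, confidence = 0.9)
  }
  fr <- run_fusion(do.call(rbind, rows), shape, frame_indices = 0:(n_fr - 1),
                   N = N, keep_maps = TRUE)
  vals <- vapply(fr$maps, function(m) m[7, 7], numeric(1))
  after <- vals[(N + 1):n_fr]
  expect_gte(mean(after >= 0.05), 0.99)
})
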