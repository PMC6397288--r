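## Temporal fusion. Per-detector binary heat maps are averaged into a
## combined frame map I(t); the accumulated evidence map follows the
## registered exponential moving average
##
##     A(t) = I(t) / N + ((N - 1) / N) * A(t - 1),
##
## with A(t - 1) first warped into frame-t coordinates through the
## inter-frame homography. When registration fails the accumulator is
## reset: A(t) = I(t). N sets the temporal memory; the default N = 9 is one
## second of history at a 9 Hz thermal camera.

#' Combine per-detector heat maps
#'
#' Pixel-wise arithmetic mean of the detectors' binary maps (with two
#' detectors, values are 0, 0.5 or 1), so a pixel's value is the fraction
#' of detectors reporting it. `method = "union"` takes the maximum instead.
#'
#' @param maps list of numeric matrices of identical shape.
#' @param method `"mean"` (default) or `"union"`.
#' @return combined numeric matrix.
#' @export
combine_heatmaps <- function(maps, method = c("mean", "union")) {
  method <- match.arg(method)
  if (!length(maps)) stop("need at least one heat map", call. = FALSE)
  d <- dim(maps[[1]])
  for (m in maps) if (!all(dim(m) == d))
    stop("heat maps must share one shape", call. = FALSE)
  if (length(maps) == 1) return(maps[[1]])
  out <- maps[[1]]
  if (method == "mean") {
    for (m in maps[-1]) out <- out + m
    out / length(maps)
  } else {
    for (m in maps[-1]) out <- pmax(out, m)
    out
  }
}

#' Accumulator state
#'
#' `accumulator_init()` starts the state at the first frame's combined map
#' (equivalent to a reset at t = 0); [update_accumulator()] advances it.
#'
#' @param I0 combined heat map of the first frame.
#' @param N positive integer update constant (temporal memory).
#' @param frame_index index of the first frame.
#' @return list of class `accumulator_state` with fields `A`, `N`,
#'   `last_frame`, `resets`, `updates`.
#' @export
accumulator_init <- function(I0, N = 9, frame_index = 0L) {
  if (N < 1) stop("N must be >= 1", call. = FALSE)
  structure(list(A = I0, N = as.integer(N),
                 last_frame = as.integer(frame_index),
                 resets = 0L, updates = 0L),
            class = "accumulator_state")
}

#' Advance the accumulator by one frame
#'
#' If `reg` carries a homography, the previous accumulated map is warped
#' into the new frame's coordinates and blended,
#' `A(t) = I(t)/N + ((N-1)/N) A(t-1)`; pixels warped in from outside the
#' previous frame contribute 0, so evidence decays at the leading frame
#' edge. If registration is absent the accumulator resets to `A(t) = I(t)`.
#'
#' @param state `accumulator_state`.
#' @param I_t combined heat map at the new frame.
#' @param reg `registration_result` for previous -> current frame, or
#'   `NULL` to force a reset.
#' @param frame_index index of the new frame.
#' @return updated `accumulator_state`.
#' @export
update_accumulator <- function(state, I_t, reg = NULL,
                               frame_index = state$last_frame + 1L) {
  stopifnot(inherits(state, "accumulator_state"))
  if (!all(dim(I_t) == dim(state$A)))
    stop("heat map shape changed mid-sequence", call. = FALSE)
  if (is.null(reg) || is.null(reg$homography)) {
    state$A <- I_t
    state$resets <- state$resets + 1L
  } else {
    warped <- warp_heatmap(state$A, reg$homography, dim(I_t))
    N <- state$N
    state$A <- clamp01(I_t / N + (N - 1) / N * warped)
  }
  state$updates <- state$updates + 1L
  state$last_frame <- as.integer(frame_index)
  state
}

#' Stream a detection sequence through fusion and accumulation
#'
#' Drives the per-frame loop: rasterize each detector's (already
#' confidence-filtered) boxes, average them, register against the previous
#' frame (or take supplied homographies), and update the accumulator.
#' Frames with no detection entries are treated as empty detections.
#'
#' @param detections detection data frame covering all detectors.
#' @param shape frame shape `c(height, width)`.
#' @param frame_indices integer frame indices, in order; defaults to the
#'   range present in `detections`.
#' @param frames optional list of raw frames (named/ordered as
#'   `frame_indices`) used to estimate homographies when `homographies` is
#'   not supplied; with neither, the camera is assumed static (identity).
#' @param homographies optional list of [homography()] objects, entry `t`
#'   mapping frame `t-1` to frame `t` (first entry unused or NA).
#' @param N accumulator constant.
#' @param combine `"mean"` or `"union"`.
#' @param detector_ids detectors expected per frame; defaults to those in
#'   `detections`.
#' @param on_state optional callback `function(t, state, reg)` run after
#'   each update (used by the pipeline to extract candidates in-stream).
#' @param keep_maps keep every accumulated map in the result (memory-heavy
#'   for long sequences).
#' @return object of class `fusion_run`: list with final `state`,
#'   per-frame `diagnostics` data frame (`frame, n_boxes, reset,
#'   num_matches, reproj_err`), and `maps` (list, if `keep_maps`).
#' @export
run_fusion <- function(detections, shape, frame_indices = NULL,
                       frames = NULL, homographies = NULL, N = 9,
                       combine = c("mean", "union"), detector_ids = NULL,
                       on_state = NULL, keep_maps = FALSE) {
  combine <- match.arg(combine)
  shape <- stop_if_not_shape(shape)
  validate_detections(detections)
  if (is.null(frame_indices)) {
    frame_indices <- if (nrow(detections))
      seq(min(detections$frame), max(detections$frame)) else integer()
  }
  if (is.null(detector_ids)) {
    detector_ids <- sort(unique(detections$detector_id))
    if (!length(detector_ids)) detector_ids <- "detector"
  }
  state <- NULL
  feat_prev <- NULL
  diags <- vector("list", length(frame_indices))
  maps <- if (keep_maps) vector("list", length(frame_indices)) else NULL
  for (k in seq_along(frame_indices)) {
    t <- frame_indices[k]
    fr_dets <- detections[detections$frame == t, , drop = FALSE]
    per_det <- lapply(detector_ids, function(d)
      rasterize_boxes(fr_dets[fr_dets$detector_id == d, , drop = FALSE],
                      shape))
    I_t <- combine_heatmaps(per_det, method = combine)
    reg <- NULL
    if (k > 1) {
      if (!is.null(homographies)) {
        h <- homographies[[k]]
        reg <- if (is.null(h) || (length(h) == 1 && is.na(h))) NULL
               else registration_from_homography(h)
      } else if (!is.null(frames)) {
        if (is.null(feat_prev)) feat_prev <- frame_features(frames[[k - 1]])
        feat_cur <- frame_features(frames[[k]])
        reg <- match_features(feat_prev, feat_cur)
        feat_prev <- feat_cur
        if (is.null(reg$homography)) reg <- NULL
      } else {
        reg <- registration_from_homography(homography_identity())
      }
    }
    if (k == 1) {
      state <- accumulator_init(I_t, N = N, frame_index = t)
    } else {
      state <- update_accumulator(state, I_t, reg, frame_index = t)
    }
    diags[[k]] <- data.frame(
      frame = t, n_boxes = nrow(fr_dets),
      reset = k > 1 && (is.null(reg) || is.null(reg$homography)),
      num_matches = if (!is.null(reg)) reg$num_matches else NA_integer_,
      reproj_err = if (!is.null(reg)) reg$reproj_err else NA_real_)
    if (keep_maps) maps[[k]] <- state$A
    if (!is.null(on_state)) on_state(t, state, reg)
  }
  structure(list(state = state, diagnostics = do.call(rbind, diags),
                 maps = maps, frame_indices = frame_indices),
            class = "fusion_run")
}

#' @export
print.fusion_run <- function(x, ...) {
  n <- length(x$frame_indices)
  cat("fusion run:", n, "frames, N =", x$state$N,
      "| resets:", x$state$resets, "\n")
  if (n) cat(sprintf("  final max evidence: %.3f\n", max(x$state$A)))
  invisible(x)
}
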