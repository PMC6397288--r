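## Greedy multi-object tracking of candidate signatures, so each persistent
## warm object yields one detection event rather than one per frame. Track
## positions are motion-compensated through the inter-frame homography
## before gating; without compensation the camera's own motion (several
## pixels per frame) would break association.

new_tracker <- function(gate_px = 15, max_missed = 5) {
  structure(list(tracks = list(), next_id = 1L,
                 gate_px = gate_px, max_missed = max_missed),
            class = "tracker")
}

new_track <- function(id, frame, cand) {
  list(id = id, state = "active", missed = 0L,
       pos = c(cand$cx, cand$cy),          # in current-frame coordinates
       disp_sum = 0, disp_n = 0L,
       members = data.frame(frame = frame, cx = cand$cx, cy = cand$cy,
                            w = cand$w, h = cand$h,
                            mean_heat = cand$mean_heat))
}

#' One greedy association step
#'
#' Active tracks' last positions are warped into the current frame through
#' `h` (previous -> current); all (track, candidate) pairs are sorted by
#' center distance and accepted greedily while the distance is within
#' `gate_px` and neither member is already consumed. Ties break to the
#' lower track id, then the lower candidate id. Unmatched candidates spawn
#' new tracks; unmatched tracks accrue a missed frame and close after
#' `max_missed`.
#'
#' @param tracker tracker state from `new_tracker()`.
#' @param cands candidate data frame from [extract_candidates()].
#' @param frame current frame index.
#' @param h [homography()] mapping the previous frame to this frame
#'   (`NULL` for identity / first frame).
#' @return updated tracker.
#' @export
associate_step <- function(tracker, cands, frame, h = NULL) {
  stopifnot(inherits(tracker, "tracker"))
  active <- which(vapply(tracker$tracks, function(tr) tr$state == "active",
                         logical(1)))
  ## motion-compensate every active track into current-frame coordinates
  if (!is.null(h) && length(active)) {
    pos <- t(vapply(tracker$tracks[active], function(tr) tr$pos, numeric(2)))
    warped <- apply_homography(h, pos)
    for (k in seq_along(active))
      tracker$tracks[[active[k]]]$pos <- warped[k, ]
  }
  n_tr <- length(active); n_cd <- nrow(cands)
  used_tr <- logical(n_tr); used_cd <- logical(n_cd)
  if (n_tr && n_cd) {
    pos <- t(vapply(tracker$tracks[active], function(tr) tr$pos, numeric(2)))
    dx <- outer(pos[, 1], cands$cx, "-")
    dy <- outer(pos[, 2], cands$cy, "-")
    D <- sqrt(dx^2 + dy^2)
    ids <- vapply(tracker$tracks[active], function(tr) tr$id, integer(1))
    ord <- order(as.vector(D), ids[row(D)], col(D))
    for (p in ord) {
      ti <- row(D)[p]; ci <- col(D)[p]
      if (D[p] > tracker$gate_px) break
      if (used_tr[ti] || used_cd[ci]) next
      used_tr[ti] <- TRUE; used_cd[ci] <- TRUE
      tr <- tracker$tracks[[active[ti]]]
      gap <- frame - tr$members$frame[nrow(tr$members)]
      tr$disp_sum <- tr$disp_sum + D[p] / max(gap, 1)
      tr$disp_n <- tr$disp_n + 1L
      tr$missed <- 0L
      tr$pos <- c(cands$cx[ci], cands$cy[ci])
      tr$members <- rbind(tr$members,
                          data.frame(frame = frame, cx = cands$cx[ci],
                                     cy = cands$cy[ci], w = cands$w[ci],
                                     h = cands$h[ci],
                                     mean_heat = cands$mean_heat[ci]))
      tracker$tracks[[active[ti]]] <- tr
    }
  }
  ## unmatched tracks age; close at the missed budget
  for (k in seq_len(n_tr)) {
    if (used_tr[k]) next
    tr <- tracker$tracks[[active[k]]]
    tr$missed <- tr$missed + 1L
    if (tr$missed >= tracker$max_missed) tr$state <- "closed"
    tracker$tracks[[active[k]]] <- tr
  }
  ## unmatched candidates spawn tracks (in candidate order)
  for (ci in seq_len(n_cd)) {
    if (used_cd[ci]) next
    tracker$tracks[[length(tracker$tracks) + 1L]] <-
      new_track(tracker$next_id, frame, cands[ci, , drop = FALSE])
    tracker$next_id <- tracker$next_id + 1L
  }
  tracker
}

close_all_tracks <- function(tracker) {
  for (k in seq_along(tracker$tracks)) tracker$tracks[[k]]$state <- "closed"
  tracker
}

#' Finalize tracks into detection events
#'
#' Tracks spanning at least `min_length` member frames become events.
#' The representative pixel position is the median member's centroid; the
#' reported displacement is the mean camera-compensated centroid step in
#' px/frame (computed during association, after homography compensation).
#'
#' @param tracker tracker with all tracks closed.
#' @param min_length minimum member count for an event.
#' @param survey_id stamped on the output.
#' @return data frame of events: `survey_id, track_id, first_frame,
#'   last_frame, length, frame, cx, cy, mean_w, mean_h, disp_px_per_frame`,
#'   with the member tables attached as attribute `"members"` (named by
#'   track id).
#' @export
finalize_events <- function(tracker, min_length = 2, survey_id = "survey") {
  stopifnot(inherits(tracker, "tracker"))
  rows <- list(); members <- list()
  for (tr in tracker$tracks) {
    stopifnot(tr$state == "closed")
    n <- nrow(tr$members)
    if (n < min_length) next
    med <- ceiling(n / 2)                    # median member
    rows[[length(rows) + 1L]] <- data.frame(
      survey_id = survey_id, track_id = tr$id,
      first_frame = tr$members$frame[1], last_frame = tr$members$frame[n],
      length = n, frame = tr$members$frame[med],
      cx = tr$members$cx[med], cy = tr$members$cy[med],
      mean_w = mean(tr$members$w), mean_h = mean(tr$members$h),
      disp_px_per_frame = if (tr$disp_n) tr$disp_sum / tr$disp_n else 0)
    members[[as.character(tr$id)]] <- tr$members
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(survey_id = character(), track_id = integer(),
               first_frame = integer(), last_frame = integer(),
               length = integer(), frame = integer(), cx = numeric(),
               cy = numeric(), mean_w = numeric(), mean_h = numeric(),
               disp_px_per_frame = numeric())
  row.names(out) <- NULL
  attr(out, "members") <- members
  out
}
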