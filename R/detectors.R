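## Detector interface. External detections (e.g. from neural-network object
## detectors run elsewhere) are exchanged as long-format data frames with
## columns survey_id, frame, detector_id, label, x0, y0, x1, y1, confidence.
## A classical intensity-blob detector is bundled so the whole pipeline can
## run without any trained model.

detection_cols <- c("survey_id", "frame", "detector_id", "label",
                    "x0", "y0", "x1", "y1", "confidence")

empty_detections <- function() {
  data.frame(survey_id = character(), frame = integer(),
             detector_id = character(), label = character(),
             x0 = numeric(), y0 = numeric(), x1 = numeric(), y1 = numeric(),
             confidence = numeric())
}

validate_detections <- function(dets) {
  if (!all(detection_cols %in% names(dets)))
    stop("detections need columns: ", paste(detection_cols, collapse = ", "),
         call. = FALSE)
  bad <- which(!is.finite(dets$confidence) | dets$confidence < 0 |
                 dets$confidence > 1)
  if (length(bad))
    stop("confidence outside [0,1] at row ", bad[1], call. = FALSE)
  bad <- which(dets$x0 >= dets$x1 | dets$y0 >= dets$y1)
  if (length(bad))
    stop("degenerate box at row ", bad[1], call. = FALSE)
  invisible(dets[detection_cols])
}

#' Filter detections by confidence
#'
#' Drops detections strictly below `threshold`; a detection exactly at the
#' threshold is retained. The default 0.05 is deliberately permissive — the
#' pipeline relies on temporal accumulation, not a high per-frame cut, to
#' suppress spurious boxes.
#'
#' @param dets detection data frame (see [read_detections()]).
#' @param threshold confidence cut in `[0, 1]`.
#' @return filtered detection data frame, input order preserved.
#' @export
filter_by_confidence <- function(dets, threshold = 0.05) {
  stopifnot(threshold >= 0, threshold <= 1)
  validate_detections(dets)
  dets[dets$confidence >= threshold, , drop = FALSE]
}

#' Classical warm-blob detector
#'
#' A trained-model-free baseline detector: thresholds a 16-bit thermal frame
#' at `intensity_threshold` (raw counts), labels 8-connected super-threshold
#' regions, and returns a bounding box for every region whose width and
#' height fall within the size gate. Confidence is the region's mean excess
#' intensity normalized by the frame's maximum excess, in `[0, 1]`.
#'
#' @param frame integer/numeric matrix of raw thermal counts.
#' @param intensity_threshold counts above which a pixel is considered warm.
#' @param min_width,max_width inclusive box-size gate in pixels.
#' @param frame_index,survey_id,detector_id metadata stamped on the output.
#' @return detection data frame.
#' @export
detect_blobs <- function(frame, intensity_threshold, min_width = 3,
                         max_width = 30, frame_index = 0L,
                         survey_id = "survey", detector_id = "blob") {
  lab <- label_components(frame > intensity_threshold, connectivity = 8)
  k <- max(lab)
  out <- empty_detections()
  if (!k) return(out)
  top <- max(frame)
  scale <- max(top - intensity_threshold, 1)
  hgt <- nrow(frame)
  idx <- which(lab > 0)
  comp <- lab[idx]
  px_x <- (idx - 1L) %/% hgt
  px_y <- (idx - 1L) %% hgt
  for (ci in seq_len(k)) {
    sel <- comp == ci
    xs <- px_x[sel]; ys <- px_y[sel]
    w <- max(xs) - min(xs) + 1L; h <- max(ys) - min(ys) + 1L
    if (w < min_width || w > max_width || h < min_width || h > max_width)
      next
    conf <- clamp01(mean(frame[idx[sel]] - intensity_threshold) / scale)
    out[nrow(out) + 1L, ] <- list(survey_id, as.integer(frame_index),
                                  detector_id, "koala",
                                  min(xs), min(ys), max(xs) + 1, max(ys) + 1,
                                  conf)
  }
  out
}

#' Read and write detection files
#'
#' The CSV dialect has columns
#' `survey_id,frame,detector_id,label,x0,y0,x1,y1,confidence`; the JSON
#' dialect is a list of per-frame objects `{frame, detections: [...]}` with
#' the same fields. Both round-trip bit-exactly. Malformed rows (missing
#' fields, confidence outside `[0, 1]`, degenerate boxes) raise an error
#' naming the offending row.
#'
#' @param path file path.
#' @param dets detection data frame.
#' @return `read_detections()` returns the detection data frame.
#' @export
read_detections <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    frames <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    rows <- lapply(frames, function(fr) {
      do.call(rbind, lapply(fr$detections, function(d)
        data.frame(survey_id = d$survey_id, frame = as.integer(fr$frame),
                   detector_id = d$detector_id, label = d$label,
                   x0 = as.numeric(d$x0), y0 = as.numeric(d$y0),
                   x1 = as.numeric(d$x1), y1 = as.numeric(d$y1),
                   confidence = as.numeric(d$confidence))))
    })
    dets <- do.call(rbind, rows)
    if (is.null(dets)) dets <- empty_detections()
  } else {
    dets <- read_csv_plain(path, colClasses = c(
      survey_id = "character", frame = "integer",
      detector_id = "character", label = "character",
      x0 = "numeric", y0 = "numeric", x1 = "numeric", y1 = "numeric",
      confidence = "numeric"))
  }
  validate_detections(dets)
  row.names(dets) <- NULL
  dets
}

#' @rdname read_detections
#' @export
write_detections <- function(dets, path) {
  validate_detections(dets)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    frames <- split(dets, dets$frame)
    payload <- lapply(frames, function(fr) {
      list(frame = fr$frame[1],
           detections = lapply(seq_len(nrow(fr)), function(i)
             as.list(fr[i, detection_cols])))
    })
    names(payload) <- NULL
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17))
  } else {
    write_csv_exact(dets[detection_cols], path)
  }
  invisible(path)
}
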