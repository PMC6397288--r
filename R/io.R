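## On-disk survey bundles. A fixture directory holds 16-bit grayscale TIFF
## frames with zero-padded numeric names, CSV telemetry / truth / object
## tables, the true homography list, a YAML manifest (file map, terrain
## descriptor, config echo), and optionally detection files. Everything is
## plain text except the TIFFs, and write -> read reproduces the bundle
## exactly.

#' Read and write 16-bit frame stacks
#'
#' Frames are single-page 16-bit grayscale TIFFs; raw integer counts
#' round-trip exactly.
#'
#' @param frames list of integer matrices (counts 0..65535).
#' @param dir directory to hold `frame_NNNNNN.tif` files.
#' @param indices 0-based frame indices used in the file names.
#' @return `write_frames()` the file names; `read_frames()` the frame list.
#' @export
write_frames <- function(frames, dir, indices = seq_along(frames) - 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- sprintf("frame_%06d.tif", indices)
  for (k in seq_along(frames))
    tiff::writeTIFF(frames[[k]] / 65535, file.path(dir, files[k]),
                    bits.per.sample = 16L, compression = "none")
  files
}

#' @rdname write_frames
#' @param files frame file names, in frame order.
#' @export
read_frames <- function(dir, files = NULL) {
  if (is.null(files)) files <- sort(list.files(dir, pattern = "\\.tif$"))
  lapply(files, function(f) {
    m <- tiff::readTIFF(file.path(dir, f), as.is = TRUE)
    matrix(as.integer(m), nrow(m), ncol(m))
  })
}

homographies_to_df <- function(hs) {
  rows <- lapply(seq_along(hs), function(t) {
    h <- hs[[t]]
    if (is.null(h) || (length(h) == 1 && is.na(h))) return(NULL)
    v <- as.numeric(t(unclass(h)))
    data.frame(frame = t - 1L, h11 = v[1], h12 = v[2], h13 = v[3],
               h21 = v[4], h22 = v[5], h23 = v[6],
               h31 = v[7], h32 = v[8], h33 = v[9])
  })
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}

df_to_homographies <- function(df, n_frames) {
  hs <- vector("list", n_frames)
  hs[[1]] <- NA
  for (i in seq_len(nrow(df))) {
    m <- matrix(as.numeric(df[i, c("h11", "h12", "h13", "h21", "h22",
                                   "h23", "h31", "h32", "h33")]),
                3, 3, byrow = TRUE)
    hs[[df$frame[i] + 1L]] <- homography(m)
  }
  hs
}

terrain_to_list <- function(terrain) {
  if (is.null(terrain)) return(NULL)
  unclass(terrain)
}

terrain_from_list <- function(x) {
  if (is.null(x)) return(NULL)
  if (x$type == "east_threshold") return(terrain_open_east(x$east_min))
  terrain_raster(do.call(rbind, x$mask), unlist(x$origin), x$res)
}

#' Write and read a synthetic survey fixture
#'
#' Serializes a [generate_survey()] bundle to a directory (frames as TIFF,
#' tables as CSV, manifest as YAML, with the scene configuration echoed for
#' provenance) and reads it back exactly.
#'
#' @param survey `thermal_survey`.
#' @param dir fixture directory.
#' @return `write_fixture()` returns the manifest (invisibly);
#'   `read_fixture()` the reconstructed `thermal_survey`.
#' @export
write_fixture <- function(survey, dir) {
  stopifnot(inherits(survey, "thermal_survey"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- write_frames(survey$frames, file.path(dir, "frames"),
                        survey$telemetry$frame)
  write_csv_exact(survey$telemetry, file.path(dir, "telemetry.csv"))
  write_csv_exact(survey$truth, file.path(dir, "truth.csv"))
  write_csv_exact(survey$objects, file.path(dir, "objects.csv"))
  hdf <- homographies_to_df(survey$homographies)
  if (!is.null(hdf)) write_csv_exact(hdf, file.path(dir,
                                                    "homographies.csv"))
  ## ground-truth animal positions in the survey dialect
  an <- survey$objects[survey$objects$class == "animal", , drop = FALSE]
  gt <- data.frame(survey_id = rep(survey$config$survey_id, nrow(an)),
                   animal_id = an$object_id, lat = an$lat, lon = an$lon,
                   collared = rep(TRUE, nrow(an)))
  write_csv_exact(gt, file.path(dir, "ground_truth.csv"))
  cfg <- unclass(survey$config)
  manifest <- list(
    survey_id = survey$config$survey_id,
    n_frames = length(survey$frames),
    frame_shape = as.integer(survey$config$frame_shape),
    frames = as.list(stats::setNames(files,
                                     sprintf("f%06d",
                                             survey$telemetry$frame))),
    tables = list(telemetry = "telemetry.csv", truth = "truth.csv",
                  objects = "objects.csv",
                  ground_truth = "ground_truth.csv",
                  homographies = if (is.null(hdf)) NULL else
                    "homographies.csv"),
    terrain = terrain_to_list(survey$terrain),
    config = cfg[!vapply(cfg, is.null, logical(1))])
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(manifest)
}

#' @rdname write_fixture
#' @export
read_fixture <- function(dir) {
  manifest <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  cfg_in <- manifest$config
  cfg_args <- cfg_in[names(cfg_in) %in% names(formals(scene_config))]
  for (nm in c("extent_m", "animal_width_px", "frame_shape", "ref_latlon",
               "conf_true", "conf_false"))
    if (!is.null(cfg_args[[nm]])) cfg_args[[nm]] <- unlist(cfg_args[[nm]])
  cfg <- do.call(scene_config, cfg_args)
  frames <- read_frames(file.path(dir, "frames"),
                        unname(unlist(manifest$frames)))
  telemetry <- read_csv_plain(file.path(dir, "telemetry.csv"), colClasses = c(
    frame = "integer", timestamp = "numeric", lat = "numeric",
    lon = "numeric", alt_agl = "numeric", heading_deg = "numeric"))
  truth <- read_csv_plain(file.path(dir, "truth.csv"), colClasses = c(
    frame = "integer", object_id = "character", class = "character",
    x0 = "numeric", y0 = "numeric", x1 = "numeric", y1 = "numeric",
    visible = "logical"))
  objects <- read_csv_plain(file.path(dir, "objects.csv"), colClasses = c(
    object_id = "character", class = "character", east0 = "numeric",
    north0 = "numeric", ve = "numeric", vn = "numeric",
    width_px = "numeric", contrast_scale = "numeric", lat = "numeric",
    lon = "numeric"))
  hs <- NULL
  hpath <- file.path(dir, "homographies.csv")
  if (file.exists(hpath))
    hs <- df_to_homographies(read_csv_plain(hpath), length(frames))
  structure(list(frames = frames, truth = truth, objects = objects,
                 telemetry = telemetry, homographies = hs,
                 terrain = terrain_from_list(manifest$terrain),
                 path = NULL,
                 ref = local_ref(cfg$ref_latlon[1], cfg$ref_latlon[2]),
                 config = cfg),
            class = "thermal_survey")
}

#' Write events as GeoJSON points
#'
#' @param events georeferenced event data frame with `lat`, `lon`,
#'   `label`, `matched_animal`.
#' @param path output file.
#' @export
write_events_geojson <- function(events, path) {
  feats <- lapply(seq_len(nrow(events)), function(i) {
    e <- events[i, ]
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(e$lon, e$lat)),
         properties = list(track_id = e$track_id, label = e$label,
                           matched_animal =
                             if (is.na(e$matched_animal)) NULL
                             else e$matched_animal,
                           length = e$length,
                           first_frame = e$first_frame,
                           last_frame = e$last_frame))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a ground-truth animal CSV
#'
#' Dialect: `survey_id,animal_id,lat,lon,collared`.
#'
#' @param path CSV path.
#' @return data frame.
#' @export
read_ground_truth <- function(path) {
  gt <- read_csv_plain(path)
  need <- c("survey_id", "animal_id", "lat", "lon")
  if (!all(need %in% names(gt)))
    stop("ground truth needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  gt
}
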