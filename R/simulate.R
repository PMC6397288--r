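## Synthetic aerial thermal survey generator. Emulates the data a
## low-altitude thermal survey produces — 16-bit frames of warm compact
## animals in textured cool canopy, larger fast-moving distractors on open
## ground, a translating (optionally slowly rotating) nadir camera flying a
## lawnmower pattern, telemetry, exact per-frame homographies, and noisy
## mock detectors — so every pipeline stage can be tested against known
## truth without field data or trained networks.

#' Synthetic scene configuration
#'
#' Camera defaults follow a typical small-RPAS thermal survey: 60 m above
#' ground, 8 m/s, 9 Hz, 640 x 512 px frames. The ground sampling distance
#' default of 0.08 m/px matches a 13 mm lens with a 17 um-pitch detector
#' at that altitude. Thermal values are raw 16-bit counts; animals sit
#' `animal_contrast` counts above the canopy mean.
#'
#' @param seed RNG seed; identical config + seed gives bit-identical
#'   surveys.
#' @param extent_m world extent `c(east, north)` in metres.
#' @param n_animals number of (static, canopy-dwelling) animals.
#' @param animal_width_px range of animal signature widths, px.
#' @param animal_contrast animal excess over canopy mean, counts.
#' @param bg_mean,bg_sd,bg_scale_px canopy texture: mean counts, amplitude,
#'   spatial correlation scale (Gaussian blur sigma, px).
#' @param open_frac eastern fraction of the world that is open terrain.
#' @param open_mean,open_sd,open_scale_px open-ground texture parameters.
#' @param sensor_noise_sd per-frame iid sensor noise, counts (0 = none).
#' @param occlusion_prob per-animal, per-frame probability of being hidden
#'   by canopy.
#' @param n_kangaroos,kangaroo_width_px,kangaroo_speed_ms fast, wide
#'   distractors on open ground.
#' @param n_cars,car_width_px,car_speed_ms vehicle-scale distractors.
#' @param n_humans,human_width_px,human_speed_ms person-scale distractors.
#' @param altitude_m,speed_ms,frame_rate_hz,frame_shape,gsd camera model;
#'   `frame_shape` is `c(height, width)`.
#' @param rot_amp_deg,rot_period_frames sinusoidal heading wobble
#'   (amplitude degrees, period frames); 0 disables rotation.
#' @param transect_spacing_m lawnmower spacing; default 80% of the
#'   across-track footprint.
#' @param n_frames cap on total frames (default: the full pattern).
#' @param ref_latlon `c(lat, lon)` of the local origin.
#' @param survey_id survey identifier.
#' @return list of class `scene_config`.
#' @export
scene_config <- function(seed = 1,
                         extent_m = c(100, 250),
                         n_animals = 10,
                         animal_width_px = c(5, 12),
                         animal_contrast = 12000,
                         bg_mean = 20000, bg_sd = 1500, bg_scale_px = 4,
                         open_frac = 0.25, open_mean = 18500,
                         open_sd = 500, open_scale_px = 10,
                         sensor_noise_sd = 200,
                         occlusion_prob = 0,
                         n_kangaroos = 1, kangaroo_width_px = 24,
                         kangaroo_speed_ms = 4,
                         n_cars = 0, car_width_px = 45, car_speed_ms = 8,
                         n_humans = 0, human_width_px = 8,
                         human_speed_ms = 1.5,
                         altitude_m = 60, speed_ms = 8, frame_rate_hz = 9,
                         frame_shape = c(512, 640), gsd = 0.08,
                         rot_amp_deg = 0, rot_period_frames = 40,
                         transect_spacing_m = NULL, n_frames = NULL,
                         ref_latlon = c(-27.267, 152.975),
                         survey_id = "sim") {
  cfg <- as.list(environment())
  if (any(extent_m <= 0)) stop("extent_m must be positive", call. = FALSE)
  if (frame_rate_hz <= 0) stop("frame_rate_hz must be > 0", call. = FALSE)
  if (gsd <= 0) stop("gsd must be > 0", call. = FALSE)
  if (occlusion_prob < 0 || occlusion_prob > 1 || open_frac < 0 ||
        open_frac > 1)
    stop("rates must lie in [0, 1]", call. = FALSE)
  if (any(animal_width_px <= 0)) stop("blob widths must be positive",
                                      call. = FALSE)
  cfg$frame_shape <- stop_if_not_shape(frame_shape)
  class(cfg) <- "scene_config"
  cfg
}

## Pixel -> ground affine for one camera pose, as a 3x3 matrix acting on
## (px, py, 1) and yielding (east, north, 1).
pose_matrix <- function(east, north, heading_deg, shape, gsd) {
  cx <- (shape[2] - 1) / 2; cy <- (shape[1] - 1) / 2
  th <- heading_deg * pi / 180
  ## east  = E + (px - cx) gsd cos(th) - (py - cy) gsd sin(th)
  ## north = N - (px - cx) gsd sin(th) - (py - cy) gsd cos(th)
  m <- diag(3)
  m[1, 1] <- gsd * cos(th);  m[1, 2] <- -gsd * sin(th)
  m[2, 1] <- -gsd * sin(th); m[2, 2] <- -gsd * cos(th)
  m[1, 3] <- east - cx * m[1, 1] - cy * m[1, 2]
  m[2, 3] <- north - cx * m[2, 1] - cy * m[2, 2]
  m
}

## Lawnmower flight path sampled at the frame rate.
camera_path <- function(cfg) {
  shape <- cfg$frame_shape
  along <- shape[1] * cfg$gsd
  across <- shape[2] * cfg$gsd
  spacing <- if (is.null(cfg$transect_spacing_m)) 0.8 * across
             else cfg$transect_spacing_m
  me <- across / 2; mn <- along / 2
  easts <- if (cfg$extent_m[1] <= 2 * me) cfg$extent_m[1] / 2
           else seq(me, cfg$extent_m[1] - me, by = spacing)
  step <- cfg$speed_ms / cfg$frame_rate_hz
  n0 <- mn; n1 <- max(cfg$extent_m[2] - mn, n0)
  norths_up <- seq(n0, n1, by = step)
  rows <- list()
  for (k in seq_along(easts)) {
    up <- k %% 2 == 1
    ns <- if (up) norths_up else rev(norths_up)
    rows[[k]] <- data.frame(east = easts[k], north = ns,
                            heading = if (up) 0 else 180)
  }
  path <- do.call(rbind, rows)
  if (!is.null(cfg$n_frames)) path <- path[seq_len(min(cfg$n_frames,
                                                       nrow(path))), ]
  n <- nrow(path)
  path$frame <- seq_len(n) - 1L
  path$timestamp <- path$frame / cfg$frame_rate_hz
  if (cfg$rot_amp_deg != 0)
    path$heading <- path$heading +
      cfg$rot_amp_deg * sin(2 * pi * path$frame / cfg$rot_period_frames)
  row.names(path) <- NULL
  path
}

## Correlated random texture: blurred white noise rescaled to a target sd.
make_texture <- function(nr, nc, mean, sd, scale_px) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (scale_px > 0) z <- gblur_mat(z, scale_px)
  s <- stats::sd(as.vector(z))
  if (s > 0) z <- z / s
  mean + sd * z
}

## Place scene objects; animals in canopy, distractors on open ground.
place_objects <- function(cfg, open_east) {
  rows <- list()
  add <- function(class, n, width, speed, contrast_scale, in_open) {
    if (n < 1) return()
    e_lo <- if (in_open) min(open_east + 2, cfg$extent_m[1] - 2) else 2
    e_hi <- if (in_open) cfg$extent_m[1] - 2 else max(open_east - 2, 4)
    for (i in seq_len(n)) {
      ang <- stats::runif(1, 0, 2 * pi)
      w <- if (length(width) == 2) stats::runif(1, width[1], width[2])
           else width
      rows[[length(rows) + 1L]] <<- data.frame(
        object_id = sprintf("%s_%02d", class, i), class = class,
        east0 = stats::runif(1, e_lo, e_hi),
        north0 = stats::runif(1, 6, cfg$extent_m[2] - 6),
        ve = speed * sin(ang), vn = speed * cos(ang),
        width_px = w, contrast_scale = contrast_scale)
    }
  }
  add("animal", cfg$n_animals, cfg$animal_width_px, 0, 1, FALSE)
  add("kangaroo", cfg$n_kangaroos, cfg$kangaroo_width_px,
      cfg$kangaroo_speed_ms, 1, TRUE)
  add("car", cfg$n_cars, cfg$car_width_px, cfg$car_speed_ms, 1.1, TRUE)
  add("human", cfg$n_humans, cfg$human_width_px, cfg$human_speed_ms,
      0.9, TRUE)
  if (!length(rows))
    return(data.frame(object_id = character(), class = character(),
                      east0 = numeric(), north0 = numeric(),
                      ve = numeric(), vn = numeric(),
                      width_px = numeric(), contrast_scale = numeric()))
  do.call(rbind, rows)
}

#' Generate a synthetic thermal survey
#'
#' Renders the full survey deterministically from the configuration seed:
#' frames (16-bit counts), per-frame ground-truth boxes with visibility,
#' telemetry, the exact homography between every consecutive frame pair,
#' and a terrain descriptor for the open-ground region.
#'
#' @param cfg [scene_config()].
#' @return object of class `thermal_survey`: list with `frames` (list of
#'   integer matrices), `truth` (per-frame boxes), `objects` (world-frame
#'   object table with lat/lon), `telemetry`, `homographies` (entry t maps
#'   frame t-1 to frame t; first entry `NA`), `terrain`, `path`, `config`.
#' @export
generate_survey <- function(cfg = scene_config()) {
  stopifnot(inherits(cfg, "scene_config"))
  shape <- cfg$frame_shape
  open_east <- (1 - cfg$open_frac) * cfg$extent_m[1]
  path <- camera_path(cfg)
  n_frames <- nrow(path)
  pad <- 48L
  nr <- ceiling(cfg$extent_m[2] / cfg$gsd) + 2L * pad
  nc <- ceiling(cfg$extent_m[1] / cfg$gsd) + 2L * pad
  origin <- c(-pad * cfg$gsd, -pad * cfg$gsd)       # (east, north) of cell 0
  ref <- local_ref(cfg$ref_latlon[1], cfg$ref_latlon[2])
  cam <- camera_model(gsd = cfg$gsd)

  survey <- local_seed(cfg$seed, {
    tex <- make_texture(nr, nc, cfg$bg_mean, cfg$bg_sd, cfg$bg_scale_px)
    open_cols <- which((seq_len(nc) - 1 + 0.5) * cfg$gsd + origin[1] >=
                         open_east)
    if (length(open_cols) && cfg$open_frac > 0) {
      open_tex <- make_texture(nr, length(open_cols), cfg$open_mean,
                               cfg$open_sd, cfg$open_scale_px)
      tex[, open_cols] <- open_tex
    }
    objects <- place_objects(cfg, open_east)
    occl <- if (nrow(objects))
      matrix(stats::runif(nrow(objects) * n_frames) < cfg$occlusion_prob &
               objects$class == "animal", nrow(objects), n_frames)
    else matrix(FALSE, 0, n_frames)

    px_grid <- rep(0:(shape[2] - 1), each = shape[1])
    py_grid <- rep(0:(shape[1] - 1), times = shape[2])
    frames <- vector("list", n_frames)
    truth <- list()
    for (t in seq_len(n_frames)) {
      pose <- path[t, ]
      g <- pixel_to_ground(px_grid, py_grid, pose$east, pose$north,
                           pose$heading, shape, cam)
      tx <- (g[, "east"] - origin[1]) / cfg$gsd
      ty <- (g[, "north"] - origin[2]) / cfg$gsd
      fr <- matrix(bilinear_sample(tex, tx, ty, fill = cfg$bg_mean),
                   shape[1], shape[2])
      if (nrow(objects)) {
        oe <- objects$east0 + objects$ve * pose$timestamp
        on <- objects$north0 + objects$vn * pose$timestamp
        pp <- ground_to_pixel(oe, on, pose$east, pose$north, pose$heading,
                              shape, cam)
        for (i in seq_len(nrow(objects))) {
          r <- objects$width_px[i] / 2
          x0 <- round(pp[i, "px"] - r); x1 <- round(pp[i, "px"] + r)
          y0 <- round(pp[i, "py"] - r); y1 <- round(pp[i, "py"] + r)
          if (x1 <= x0) x1 <- x0 + 1
          if (y1 <= y0) y1 <- y0 + 1
          intersects <- x1 > 0 && x0 < shape[2] && y1 > 0 && y0 < shape[1]
          if (!intersects) next
          occluded <- occl[i, t]
          visible <- !occluded && x0 >= 0 && y0 >= 0 &&
            x1 <= shape[2] && y1 <= shape[1]
          truth[[length(truth) + 1L]] <- data.frame(
            frame = path$frame[t], object_id = objects$object_id[i],
            class = objects$class[i], x0 = x0, y0 = y0, x1 = x1, y1 = y1,
            visible = visible)
          if (occluded) next
          ## render a flat-topped blob of ~width_px extent
          win <- ceiling(r) + 3
          rc <- max(1, floor(pp[i, "py"]) - win + 1):
                min(shape[1], ceiling(pp[i, "py"]) + win + 1)
          cc <- max(1, floor(pp[i, "px"]) - win + 1):
                min(shape[2], ceiling(pp[i, "px"]) + win + 1)
          if (!length(rc) || !length(cc)) next
          dy2 <- ((rc - 1) - pp[i, "py"])^2
          dx2 <- ((cc - 1) - pp[i, "px"])^2
          d4 <- outer(dy2, dx2, "+")^2 / max(r, 0.5)^4
          fr[rc, cc] <- fr[rc, cc] +
            cfg$animal_contrast * objects$contrast_scale[i] * 2^(-d4)
        }
      }
      if (cfg$sensor_noise_sd > 0)
        fr <- fr + stats::rnorm(length(fr), sd = cfg$sensor_noise_sd)
      frames[[t]] <- matrix(as.integer(clamp(round(fr), 0, 65535)),
                            shape[1], shape[2])
    }
    list(frames = frames, objects = objects,
         truth = if (length(truth)) do.call(rbind, truth) else
           data.frame(frame = integer(), object_id = character(),
                      class = character(), x0 = numeric(), y0 = numeric(),
                      x1 = numeric(), y1 = numeric(), visible = logical()))
  })

  homographies <- vector("list", n_frames)
  homographies[[1]] <- NA
  poses <- lapply(seq_len(n_frames), function(t)
    pose_matrix(path$east[t], path$north[t], path$heading[t], shape,
                cfg$gsd))
  for (t in seq_len(n_frames)[-1])
    homographies[[t]] <- homography(solve(poses[[t]]) %*% poses[[t - 1]])

  ll <- local_to_latlon(path$east, path$north, ref)
  telemetry <- data.frame(frame = path$frame, timestamp = path$timestamp,
                          lat = ll[, "lat"], lon = ll[, "lon"],
                          alt_agl = cfg$altitude_m,
                          heading_deg = path$heading)
  objects <- survey$objects
  if (nrow(objects)) {
    oll <- local_to_latlon(objects$east0, objects$north0, ref)
    objects$lat <- oll[, "lat"]; objects$lon <- oll[, "lon"]
  } else {
    objects$lat <- numeric(); objects$lon <- numeric()
  }
  structure(list(frames = survey$frames, truth = survey$truth,
                 objects = objects, telemetry = telemetry,
                 homographies = homographies,
                 terrain = terrain_open_east(open_east),
                 path = path, ref = ref, config = cfg),
            class = "thermal_survey")
}

#' @export
print.thermal_survey <- function(x, ...) {
  cat(sprintf("thermal survey '%s': %d frames %dx%d px, %d objects (%s)\n",
              x$config$survey_id, length(x$frames),
              x$config$frame_shape[1], x$config$frame_shape[2],
              nrow(x$objects),
              paste(table(x$objects$class), names(table(x$objects$class)),
                    collapse = ", ")))
  invisible(x)
}

#' Mock detector noise model
#'
#' Stands in for a trained object detector: every visible warm object is
#' reported with probability `1 - miss_rate` as a box jittered by
#' `jitter_px`, with confidence drawn from a Beta distribution; spurious
#' boxes arrive as a Poisson process per frame with low confidences.
#' Deterministic given `seed`.
#'
#' @param detector_id name stamped on the detections.
#' @param miss_rate per visible object, per frame miss probability.
#' @param fp_rate expected spurious boxes per frame (Poisson mean).
#' @param jitter_px box-centre jitter sd, px (0 = boxes equal truth).
#' @param conf_true,conf_false Beta shape pairs for confidences.
#' @param seed RNG seed.
#' @return list of class `detector_noise`.
#' @export
detector_noise <- function(detector_id = "mock", miss_rate = 0.1,
                           fp_rate = 0.2, jitter_px = 0.5,
                           conf_true = c(5, 2), conf_false = c(1.2, 4),
                           seed = 100) {
  stopifnot(miss_rate >= 0, miss_rate <= 1, fp_rate >= 0, jitter_px >= 0)
  structure(list(detector_id = detector_id, miss_rate = miss_rate,
                 fp_rate = fp_rate, jitter_px = jitter_px,
                 conf_true = conf_true, conf_false = conf_false,
                 seed = seed),
            class = "detector_noise")
}

#' Run a mock detector over a synthetic survey
#'
#' @param survey `thermal_survey`.
#' @param noise [detector_noise()].
#' @return detection data frame (see [read_detections()]).
#' @export
run_mock_detector <- function(survey, noise = detector_noise()) {
  stopifnot(inherits(survey, "thermal_survey"),
            inherits(noise, "detector_noise"))
  shape <- survey$config$frame_shape
  sid <- survey$config$survey_id
  local_seed(noise$seed, {
    rows <- list()
    for (t in survey$telemetry$frame) {
      vt <- survey$truth[survey$truth$frame == t & survey$truth$visible, ,
                         drop = FALSE]
      if (nrow(vt)) {
        keep <- stats::runif(nrow(vt)) >= noise$miss_rate
        vt <- vt[keep, , drop = FALSE]
      }
      if (nrow(vt)) {
        for (i in seq_len(nrow(vt))) {
          x0 <- vt$x0[i]; x1 <- vt$x1[i]; y0 <- vt$y0[i]; y1 <- vt$y1[i]
          if (noise$jitter_px > 0) {
            j <- stats::rnorm(2, sd = noise$jitter_px)
            s <- 1 + stats::rnorm(1, sd = 0.05)
            cx <- (x0 + x1) / 2 + j[1]; cy <- (y0 + y1) / 2 + j[2]
            hw <- (x1 - x0) / 2 * s; hh <- (y1 - y0) / 2 * s
            x0 <- cx - hw; x1 <- cx + hw; y0 <- cy - hh; y1 <- cy + hh
          }
          conf <- stats::rbeta(1, noise$conf_true[1], noise$conf_true[2])
          x0 <- clamp(x0, 0, shape[2] - 1); x1 <- clamp(x1, x0 + 1, shape[2])
          y0 <- clamp(y0, 0, shape[1] - 1); y1 <- clamp(y1, y0 + 1, shape[1])
          rows[[length(rows) + 1L]] <- data.frame(
            survey_id = sid, frame = t, detector_id = noise$detector_id,
            label = "koala", x0 = x0, y0 = y0, x1 = x1, y1 = y1,
            confidence = conf)
        }
      }
      n_fp <- stats::rpois(1, noise$fp_rate)
      for (k in seq_len(n_fp)) {
        w <- stats::runif(1, 3, 12); h <- stats::runif(1, 3, 12)
        cx <- stats::runif(1, w, shape[2] - w)
        cy <- stats::runif(1, h, shape[1] - h)
        rows[[length(rows) + 1L]] <- data.frame(
          survey_id = sid, frame = t, detector_id = noise$detector_id,
          label = "koala", x0 = cx - w / 2, y0 = cy - h / 2,
          x1 = cx + w / 2, y1 = cy + h / 2,
          confidence = stats::rbeta(1, noise$conf_false[1],
                                    noise$conf_false[2]))
      }
    }
    if (length(rows)) do.call(rbind, rows) else empty_detections()
  })
}
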