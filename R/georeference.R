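## Georeferencing and event classification. Pixels are projected to the
## ground with a nadir pinhole model: the offset from the principal point,
## scaled by the ground sampling distance (GSD), rotated by the aircraft
## heading and added to the aircraft position. Positions are handled on a
## local tangent plane (east/north metres, WGS84 equirectangular at the
## survey reference latitude), adequate at survey scales of a few km.

#' Nadir camera model
#'
#' The GSD can be given directly, or derived from focal length, detector
#' pixel pitch and altitude (`gsd = altitude * pitch / focal`).
#'
#' @param gsd ground sampling distance, metres per pixel.
#' @param focal_mm,pitch_um,altitude_m alternative specification.
#' @return list of class `camera_model`.
#' @export
camera_model <- function(gsd = NULL, focal_mm = NULL, pitch_um = NULL,
                         altitude_m = NULL) {
  if (is.null(gsd)) {
    if (is.null(focal_mm) || is.null(pitch_um) || is.null(altitude_m))
      stop("give gsd, or focal_mm + pitch_um + altitude_m", call. = FALSE)
    gsd <- altitude_m * (pitch_um * 1e-6) / (focal_mm * 1e-3)
  }
  if (gsd <= 0) stop("GSD must be positive", call. = FALSE)
  structure(list(gsd = gsd), class = "camera_model")
}

M_PER_DEG_LAT <- 111320

local_ref <- function(lat0, lon0) list(lat0 = lat0, lon0 = lon0)

latlon_to_local <- function(lat, lon, ref) {
  cbind(east = (lon - ref$lon0) * M_PER_DEG_LAT * cos(ref$lat0 * pi / 180),
        north = (lat - ref$lat0) * M_PER_DEG_LAT)
}

local_to_latlon <- function(east, north, ref) {
  cbind(lat = ref$lat0 + north / M_PER_DEG_LAT,
        lon = ref$lon0 + east / (M_PER_DEG_LAT * cos(ref$lat0 * pi / 180)))
}

#' Project pixels to ground coordinates
#'
#' Nadir pinhole projection. The image is oriented with "up" (decreasing y)
#' along the flight heading; x increases to the right of the flight
#' direction. Heading is degrees clockwise from north.
#'
#' @param px,py pixel coordinates (0-based), vectors.
#' @param east,north aircraft ground position, metres (local frame).
#' @param heading_deg aircraft heading.
#' @param shape frame shape `c(height, width)`.
#' @param camera [camera_model()].
#' @return matrix with columns `east`, `north` (metres).
#' @export
pixel_to_ground <- function(px, py, east, north, heading_deg, shape,
                            camera) {
  shape <- stop_if_not_shape(shape)
  cx <- (shape[2] - 1) / 2
  cy <- (shape[1] - 1) / 2
  dx <- (px - cx) * camera$gsd          # metres right of heading
  df <- -(py - cy) * camera$gsd         # metres forward along heading
  th <- heading_deg * pi / 180
  cbind(east = east + dx * cos(th) + df * sin(th),
        north = north - dx * sin(th) + df * cos(th))
}

#' @rdname pixel_to_ground
#' @param e,n ground coordinates to back-project.
#' @export
ground_to_pixel <- function(e, n, east, north, heading_deg, shape, camera) {
  shape <- stop_if_not_shape(shape)
  th <- heading_deg * pi / 180
  de <- e - east; dn <- n - north
  dx <- de * cos(th) - dn * sin(th)     # metres right of heading
  df <- de * sin(th) + dn * cos(th)     # metres forward
  cbind(px = dx / camera$gsd + (shape[2] - 1) / 2,
        py = -df / camera$gsd + (shape[1] - 1) / 2)
}

## Terrain descriptor: regions of open ground (vs canopy). The bundled
## simulator uses an east-threshold strip; a raster form (origin/res/mask)
## is also accepted.
terrain_open_east <- function(east_min) {
  structure(list(type = "east_threshold", east_min = east_min),
            class = "terrain_mask")
}

terrain_raster <- function(mask, origin, res) {
  structure(list(type = "raster", mask = mask, origin = origin, res = res),
            class = "terrain_mask")
}

is_open_terrain <- function(terrain, east, north) {
  if (is.null(terrain)) return(rep(NA, length(east)))
  if (terrain$type == "east_threshold") return(east >= terrain$east_min)
  i <- floor((north - terrain$origin[2]) / terrain$res) + 1
  j <- floor((east - terrain$origin[1]) / terrain$res) + 1
  ok <- i >= 1 & i <= nrow(terrain$mask) & j >= 1 & j <= ncol(terrain$mask)
  out <- rep(FALSE, length(east))
  out[ok] <- terrain$mask[cbind(i[ok], j[ok])] != 0
  out
}

#' Classify tracked events by signature rules
#'
#' Rule cascade applied to each georeferenced event, mirroring manual
#' review criteria for aerial thermal signatures:
#' 1. *car* / *human* if the event fits the configured vehicle/person
#'    template (size and ground-speed bands, open terrain);
#' 2. *kangaroo* if on open terrain AND (displacement above the
#'    rapid-motion threshold OR width above `kangaroo_min_width` px);
#' 3. *candidate* (possible koala) if width and height lie in
#'    `[3, 30]` px AND displacement is at or below the minimal-motion
#'    threshold;
#' 4. *other* otherwise.
#' Without a terrain mask the terrain-dependent rules (1–2) are skipped
#' and a message is emitted.
#'
#' @param events event data frame (needs `mean_w`, `mean_h`,
#'   `disp_px_per_frame`, `east`, `north`).
#' @param terrain `terrain_mask` or `NULL`.
#' @param rules list of thresholds, see [classification_rules()].
#' @return character vector of labels.
#' @export
classify_events <- function(events, terrain = NULL,
                            rules = classification_rules()) {
  n <- nrow(events)
  if (!n) return(character())
  open <- is_open_terrain(terrain, events$east, events$north)
  if (is.null(terrain)) message("no terrain mask: terrain rules skipped")
  w <- pmax(events$mean_w, events$mean_h)
  disp <- events$disp_px_per_frame
  lab <- rep("other", n)
  sizes_ok <- events$mean_w >= rules$min_size &
    events$mean_w <= rules$max_size &
    events$mean_h >= rules$min_size & events$mean_h <= rules$max_size
  lab[sizes_ok & disp <= rules$minimal_px] <- "candidate"
  if (!is.null(terrain)) {
    kang <- open & (disp > rules$rapid_px | w > rules$kangaroo_min_width)
    lab[kang] <- "kangaroo"
    human <- open & w >= rules$human_width[1] & w <= rules$human_width[2] &
      disp > rules$minimal_px & disp <= rules$rapid_px
    lab[human] <- "human"
    car <- w >= rules$car_min_width
    lab[car] <- "car"
  }
  lab
}

#' Classification thresholds
#'
#' Defaults: "minimal" movement is at most 1 px/frame and "rapid" more
#' than 4 px/frame (camera-compensated); kangaroo-scale signatures exceed
#' 20 px width; car-scale exceed 35 px; human-scale are 5–18 px wide and
#' walking pace. All in pixels at the survey GSD.
#'
#' @param minimal_px,rapid_px motion thresholds, px/frame.
#' @param min_size,max_size candidate size gate, px.
#' @param kangaroo_min_width,car_min_width,human_width size bands, px.
#' @return list of thresholds.
#' @export
classification_rules <- function(minimal_px = 1, rapid_px = 4,
                                 min_size = 3, max_size = 30,
                                 kangaroo_min_width = 20,
                                 car_min_width = 35,
                                 human_width = c(5, 18)) {
  list(minimal_px = minimal_px, rapid_px = rapid_px, min_size = min_size,
       max_size = max_size, kangaroo_min_width = kangaroo_min_width,
       car_min_width = car_min_width, human_width = human_width)
}

#' Match candidate events to ground-surveyed animals
#'
#' Greedy one-to-one nearest-pair matching: all (event, animal) pairs
#' within `radius_m` are sorted by ground distance and accepted while
#' neither member is consumed. Only events labelled `candidate` are
#' eligible; unmatched candidate events are relabelled `other`.
#'
#' @param events georeferenced, classified event data frame (needs
#'   `east`, `north`, `label`).
#' @param animals data frame of ground truth with `animal_id`, `east`,
#'   `north`.
#' @param radius_m matching radius, metres.
#' @return list with `events` (labels updated, `matched_animal` column
#'   added), `matches` (event row, animal_id, distance), and
#'   `undetected_animals` (ids).
#' @export
match_to_ground_truth <- function(events, animals, radius_m = 15) {
  ev <- events
  ev$matched_animal <- rep(NA_character_, nrow(ev))
  if (!nrow(ev) || !nrow(animals)) {
    ev$label[!is.na(ev$label) & ev$label == "candidate"] <- "other"
    return(list(events = ev,
                matches = data.frame(event = integer(),
                                     animal_id = character(),
                                     dist_m = numeric()),
                undetected_animals = animals$animal_id))
  }
  elig <- which(ev$label == "candidate")
  de <- outer(ev$east[elig], animals$east, "-")
  dn <- outer(ev$north[elig], animals$north, "-")
  D <- sqrt(de^2 + dn^2)
  ord <- order(as.vector(D))
  used_e <- logical(length(elig)); used_a <- logical(nrow(animals))
  m <- list()
  for (p in ord) {
    if (D[p] > radius_m) break
    i <- row(D)[p]; j <- col(D)[p]
    if (used_e[i] || used_a[j]) next
    used_e[i] <- TRUE; used_a[j] <- TRUE
    ev$matched_animal[elig[i]] <- animals$animal_id[j]
    m[[length(m) + 1L]] <- data.frame(event = elig[i],
                                      animal_id = animals$animal_id[j],
                                      dist_m = D[p])
  }
  ev$label[elig[!used_e]] <- "other"
  list(events = ev,
       matches = if (length(m)) do.call(rbind, m) else
         data.frame(event = integer(), animal_id = character(),
                    dist_m = numeric()),
       undetected_animals = animals$animal_id[!used_a])
}
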