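## Core pixel-geometry primitives: bounding boxes, binary heat maps and
## planar homographies. A heat map (detection sense, not the statistical
## sense) is an image-sized grid in [0, 1] marking pixels covered by
## detection boxes; accumulated maps hold the temporal evidence used for
## candidate extraction.

#' Construct a bounding-box data frame
#'
#' Boxes are 0-based and half-open: a box covers pixels with
#' `x0 <= x < x1` and `y0 <= y < y1` (x rightward, y downward).
#'
#' @param x0,y0,x1,y1 numeric vectors of box corners (recycled).
#' @return data frame with columns `x0, y0, x1, y1`.
#' @export
bounding_boxes <- function(x0, y0, x1, y1) {
  df <- data.frame(x0 = as.numeric(x0), y0 = as.numeric(y0),
                   x1 = as.numeric(x1), y1 = as.numeric(y1))
  validate_boxes(df)
  df
}

validate_boxes <- function(boxes) {
  need <- c("x0", "y0", "x1", "y1")
  if (!all(need %in% names(boxes)))
    stop("boxes need columns x0, y0, x1, y1", call. = FALSE)
  if (nrow(boxes) && any(boxes$x0 >= boxes$x1 | boxes$y0 >= boxes$y1))
    stop("degenerate box: require x0 < x1 and y0 < y1", call. = FALSE)
  invisible(boxes)
}

## Intersect boxes with the frame [0,w) x [0,h); drops boxes left empty.
clip_boxes <- function(boxes, shape) {
  shape <- stop_if_not_shape(shape)
  if (!nrow(boxes)) return(boxes)
  b <- boxes
  b$x0 <- pmax(b$x0, 0); b$y0 <- pmax(b$y0, 0)
  b$x1 <- pmin(b$x1, shape[2]); b$y1 <- pmin(b$y1, shape[1])
  b[b$x0 < b$x1 & b$y0 < b$y1, , drop = FALSE]
}

#' Rasterize bounding boxes into a binary heat map
#'
#' Every pixel inside at least one box is set to 1, all others to 0;
#' overlaps do not sum. Boxes extending past the frame are clipped.
#'
#' @param boxes data frame of boxes (see [bounding_boxes()]); may be empty.
#' @param shape frame shape `c(height, width)`.
#' @return numeric matrix of 0/1 with `dim = shape`.
#' @export
rasterize_boxes <- function(boxes, shape) {
  shape <- stop_if_not_shape(shape)
  m <- matrix(0, shape[1], shape[2])
  if (is.null(boxes) || !nrow(boxes)) return(m)
  validate_boxes(boxes)
  b <- clip_boxes(boxes, shape)
  for (i in seq_len(nrow(b))) {
    rows <- (floor(b$y0[i]) + 1):ceiling(b$y1[i])
    cols <- (floor(b$x0[i]) + 1):ceiling(b$x1[i])
    ## half-open: pixel index y covered iff y0 <= y < y1
    rows <- rows[rows - 1 >= b$y0[i] & rows - 1 < b$y1[i]]
    cols <- cols[cols - 1 >= b$x0[i] & cols - 1 < b$x1[i]]
    if (length(rows) && length(cols)) m[rows, cols] <- 1
  }
  m
}

#' Euclidean distance between box centers
#'
#' @param a,b boxes as numeric vectors `c(x0, y0, x1, y1)` or one-row data
#'   frames.
#' @return distance in pixels.
#' @export
box_center_distance <- function(a, b) {
  ca <- box_center(a); cb <- box_center(b)
  sqrt(sum((ca - cb)^2))
}

box_center <- function(b) {
  if (is.data.frame(b)) b <- c(b$x0[1], b$y0[1], b$x1[1], b$y1[1])
  c((b[1] + b[3]) / 2, (b[2] + b[4]) / 2)
}

## ---- homographies -----------------------------------------------------

#' Planar homographies
#'
#' A homography is a 3x3 invertible matrix mapping homogeneous pixel
#' coordinates `(x, y, 1)` in a source frame to a target frame, normalized
#' so the bottom-right entry is 1. `homography()` validates and normalizes;
#' `homography_translation()` and `homography_similarity()` are convenience
#' constructors; `apply_homography()` maps an `n x 2` matrix of points.
#'
#' @param m numeric 3x3 matrix.
#' @return 3x3 matrix of class `homography`.
#' @export
homography <- function(m) {
  if (!is.matrix(m) || !all(dim(m) == c(3, 3)) || any(!is.finite(m)))
    stop("homography must be a finite 3x3 matrix", call. = FALSE)
  if (abs(m[3, 3]) < 1e-12 || abs(det(m)) < 1e-12)
    stop("singular homography: registration failure", call. = FALSE)
  m <- m / m[3, 3]
  class(m) <- c("homography", "matrix")
  m
}

#' @rdname homography
#' @param dx,dy translation in pixels.
#' @export
homography_translation <- function(dx, dy) {
  homography(matrix(c(1, 0, 0, 0, 1, 0, dx, dy, 1), 3, 3))
}

#' @rdname homography
#' @param theta_deg rotation angle, degrees, about `center`.
#' @param center rotation center `c(x, y)` in pixels.
#' @export
homography_similarity <- function(dx = 0, dy = 0, theta_deg = 0,
                                  center = c(0, 0)) {
  th <- theta_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  Tc <- homography_translation(-center[1], -center[2])
  Tb <- homography_translation(center[1] + dx, center[2] + dy)
  homography(Tb %*% R %*% Tc)
}

#' @rdname homography
#' @export
homography_identity <- function() homography(diag(3))

#' @rdname homography
#' @param h homography.
#' @param xy numeric `n x 2` matrix of `(x, y)` points.
#' @export
apply_homography <- function(h, xy) {
  xy <- matrix(as.numeric(xy), ncol = 2)
  p <- cbind(xy, 1) %*% t(unclass(h))
  p[, 1:2, drop = FALSE] / p[, 3]
}

invert_homography <- function(h) homography(solve(unclass(h)))

## ---- warping ----------------------------------------------------------

#' Bilinear sampling from a matrix at fractional pixel coordinates
#'
#' Samples `mat` at 0-based positions `(x, y)` (x = column, y = row),
#' returning `fill` outside the grid.
#'
#' @param mat numeric matrix.
#' @param x,y numeric vectors of equal length.
#' @param fill value used outside the source grid.
#' @return numeric vector of samples.
#' @export
bilinear_sample <- function(mat, x, y, fill = 0) {
  h <- nrow(mat); w <- ncol(mat)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0;  fy <- y - y0
  out <- rep(as.numeric(fill), length(x))
  ## a sample is valid if all four neighbours can contribute (neighbours
  ## falling just outside contribute weight 0 at the exact border)
  ok <- x >= 0 & x <= w - 1 & y >= 0 & y <= h - 1 & is.finite(x) & is.finite(y)
  if (!any(ok)) return(out)
  x0k <- x0[ok]; y0k <- y0[ok]; fxk <- fx[ok]; fyk <- fy[ok]
  x1k <- pmin(x0k + 1, w - 1); y1k <- pmin(y0k + 1, h - 1)
  idx <- function(r, c) mat[cbind(r + 1, c + 1)]
  v <- idx(y0k, x0k) * (1 - fxk) * (1 - fyk) +
       idx(y0k, x1k) * fxk * (1 - fyk) +
       idx(y1k, x0k) * (1 - fxk) * fyk +
       idx(y1k, x1k) * fxk * fyk
  out[ok] <- v
  out
}

#' Warp a heat map through a homography
#'
#' Resamples `map` into the target grid of `out_shape` by inverse mapping
#' with bilinear interpolation: output pixel `(x, y)` takes the value of the
#' source at `h^-1 (x, y)`. Pixels mapping outside the source get 0, and the
#' output is clamped to `[0, 1]`.
#'
#' @param map numeric matrix with values in `[0, 1]`.
#' @param h [homography()] mapping source coordinates to target coordinates.
#' @param out_shape target shape `c(height, width)`; defaults to `dim(map)`.
#' @return warped numeric matrix.
#' @export
warp_heatmap <- function(map, h, out_shape = dim(map)) {
  out_shape <- stop_if_not_shape(out_shape)
  hinv <- invert_homography(h)   # errors on singular input
  xs <- rep(0:(out_shape[2] - 1), each = out_shape[1])
  ys <- rep(0:(out_shape[1] - 1), times = out_shape[2])
  src <- apply_homography(hinv, cbind(xs, ys))
  v <- bilinear_sample(map, src[, 1], src[, 2], fill = 0)
  matrix(clamp01(v), out_shape[1], out_shape[2])
}
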