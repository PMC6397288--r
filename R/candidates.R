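## Candidate signature extraction: threshold the accumulated heat map,
## label 8-connected components, and keep components whose bounding box is
## between 3 and 30 pixels in both width and height — the size range of an
## arboreal-mammal thermal signature at ~60 m altitude.

#' Label connected components of a binary mask
#'
#' Two-pass union-find labeling. 8-connectivity is the default so that the
#' diagonally touching warm pixels of a single animal are not split into
#' separate components.
#'
#' @param mask logical or 0/1 numeric matrix.
#' @param connectivity 8 (default) or 4.
#' @return integer matrix of the same shape; 0 is background, components
#'   are numbered 1..k in raster (column-major) order of first pixel.
#' @export
label_components <- function(mask, connectivity = 8) {
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  h <- nrow(mask); w <- ncol(mask)
  fg <- which(mask != 0)                      # linear (column-major) indices
  lab <- matrix(0L, h, w)
  n <- length(fg)
  if (!n) return(lab)
  id_of <- integer(h * w)                     # linear index -> compact id
  id_of[fg] <- seq_len(n)
  parent <- seq_len(n)
  find <- function(i) {
    r <- i
    while (parent[r] != r) r <- parent[r]
    while (parent[i] != r) { nxt <- parent[i]; parent[i] <<- r; i <- nxt }
    r
  }
  rows <- ((fg - 1L) %% h) + 1L
  ## prior neighbours in column-major scan: up, left, and (8-conn) the
  ## two left diagonals
  offs <- list(c(-1L, 0L), c(0L, -1L))
  if (connectivity == 8) offs <- c(offs, list(c(-1L, -1L), c(1L, -1L)))
  for (o in offs) {
    nb <- fg + o[1] + o[2] * h
    ok <- nb >= 1L & nb <= h * w & (rows + o[1]) >= 1L & (rows + o[1]) <= h
    ok[ok] <- id_of[nb[ok]] > 0L
    a <- id_of[fg[ok]]; b <- id_of[nb[ok]]
    for (k in seq_along(a)) {
      ra <- find(a[k]); rb <- find(b[k])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  lab[fg] <- match(roots, unique(roots))   # fg is in raster scan order
  lab
}

#' Extract candidate signatures from an accumulated heat map
#'
#' Pixels with accumulated evidence at or above `threshold` are foreground;
#' each 8-connected component whose bounding-box width *and* height lie in
#' `[min_size, max_size]` (inclusive) becomes one candidate.
#'
#' @param A numeric matrix, accumulated heat map in `[0, 1]`.
#' @param threshold foreground threshold (boundary pixels are retained).
#' @param min_size,max_size inclusive size gate in pixels, applied to both
#'   bounding-box dimensions.
#' @return data frame with one row per candidate: `cand_id`, centroid
#'   `cx, cy` (unweighted pixel centroid, 0-based), half-open box
#'   `x0, y0, x1, y1`, `w, h`, pixel count `n_px` and `mean_heat`. The
#'   component masks (lists of linear indices) are attached as attribute
#'   `"masks"`.
#' @export
extract_candidates <- function(A, threshold = 0.05, min_size = 3,
                               max_size = 30) {
  lab <- label_components(A >= threshold, connectivity = 8)
  empty <- data.frame(cand_id = integer(), cx = numeric(), cy = numeric(),
                      x0 = numeric(), y0 = numeric(), x1 = numeric(),
                      y1 = numeric(), w = numeric(), h = numeric(),
                      n_px = integer(), mean_heat = numeric())
  k <- max(lab)
  if (!k) { attr(empty, "masks") <- list(); return(empty) }
  hgt <- nrow(A)
  idx <- which(lab > 0)
  comp <- lab[idx]
  px_x <- ((idx - 1L) %/% hgt)      # 0-based
  px_y <- ((idx - 1L) %% hgt)
  out <- empty
  masks <- list()
  next_id <- 0L
  for (ci in seq_len(k)) {
    sel <- comp == ci
    xs <- px_x[sel]; ys <- px_y[sel]
    w <- max(xs) - min(xs) + 1L
    h <- max(ys) - min(ys) + 1L
    if (w < min_size || w > max_size || h < min_size || h > max_size) next
    next_id <- next_id + 1L
    out[next_id, ] <- list(next_id, mean(xs), mean(ys),
                           min(xs), min(ys), max(xs) + 1, max(ys) + 1,
                           as.numeric(w), as.numeric(h), sum(sel),
                           mean(A[idx[sel]]))
    masks[[next_id]] <- idx[sel]
  }
  attr(out, "masks") <- masks
  out
}
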