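## Independent oracles and shared scaled-down survey configurations.

## Naive flood-fill component labeling (queue-based), deliberately
## independent of the package's union-find implementation.
flood_fill_label <- function(mask, connectivity = 8) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  nb <- if (connectivity == 8)
    expand.grid(dr = -1:1, dc = -1:1)[-5, ] else
    data.frame(dr = c(-1, 1, 0, 0), dc = c(0, 0, -1, 1))
  cur <- 0L
  for (c0 in seq_len(w)) for (r0 in seq_len(h)) {
    if (mask[r0, c0] == 0 || lab[r0, c0] != 0) next
    cur <- cur + 1L
    queue <- list(c(r0, c0))
    lab[r0, c0] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(nb))) {
        r <- p[1] + nb$dr[k]; c <- p[2] + nb$dc[k]
        if (r >= 1 && r <= h && c >= 1 && c <= w &&
              mask[r, c] != 0 && lab[r, c] == 0) {
          lab[r, c] <- cur
          queue[[length(queue) + 1L]] <- c(r, c)
        }
      }
    }
  }
  lab
}

## Partition signature invariant to label numbering.
label_signature <- function(lab) {
  groups <- split(which(lab > 0), lab[lab > 0])
  unname(groups[order(vapply(groups, min, numeric(1)))])
}

## Naive greedy assignment oracle: repeatedly take the globally closest
## unconsumed (track, candidate) pair within the gate, ties to the lower
## track id then lower candidate index.
greedy_assignment_oracle <- function(D, ids, gate) {
  pairs <- list()
  used_t <- logical(nrow(D)); used_c <- logical(ncol(D))
  repeat {
    best <- NULL
    for (i in seq_len(nrow(D))) for (j in seq_len(ncol(D))) {
      if (used_t[i] || used_c[j] || D[i, j] > gate) next
      if (is.null(best) || D[i, j] < best$d ||
            (D[i, j] == best$d && (ids[i] < ids[best$i] ||
              (ids[i] == ids[best$i] && j < best$j))))
        best <- list(i = i, j = j, d = D[i, j])
    }
    if (is.null(best)) break
    used_t[best$i] <- TRUE; used_c[best$j] <- TRUE
    pairs[[length(pairs) + 1L]] <- c(best$i, best$j)
  }
  pairs
}

## Brute-force optimal (minimum total distance) assignment by permutation
## enumeration; returns the set of matched pairs.
optimal_assignment_oracle <- function(D, gate) {
  n <- nrow(D); m <- ncol(D)
  k <- min(n, m)
  best <- NULL; best_cost <- Inf
  cols <- seq_len(m)
  perm_rows <- utils::combn(seq_len(n), k, simplify = FALSE)
  for (rows in perm_rows) {
    for (p in asplit(permutations_of(cols, k), 1)) {
      d <- D[cbind(rows, p)]
      if (any(d > gate)) next
      cost <- sum(d)
      if (cost < best_cost) {
        best_cost <- cost
        best <- cbind(rows, p)
      }
    }
  }
  best
}

permutations_of <- function(v, k) {
  if (k == 1) return(matrix(v, ncol = 1))
  out <- NULL
  for (i in seq_along(v))
    out <- rbind(out, cbind(v[i], permutations_of(v[-i], k - 1)))
  out
}

## Standard scaled-down survey: single transect fully covering a small
## world, ~74 frames, 192x256 px at 0.18 m/px (≈4.9 px/frame motion).
small_scene <- function(seed = 1, ...) {
  defaults <- list(seed = seed, extent_m = c(46, 100), n_animals = 5,
                   n_kangaroos = 1, frame_shape = c(192, 256), gsd = 0.18,
                   sensor_noise_sd = 150, open_frac = 0.25)
  do.call(scene_config, utils::modifyList(defaults, list(...)))
}

## Longest run of consecutive visible frames per object.
max_visible_run <- function(truth, object_id) {
  fr <- sort(truth$frame[truth$object_id == object_id & truth$visible])
  if (!length(fr)) return(0L)
  max(tabulate(cumsum(c(1L, diff(fr) != 1L))))
}
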