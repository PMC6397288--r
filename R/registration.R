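## Frame-to-frame registration. Consecutive frames of a moving-camera
## survey are aligned by detecting corner keypoints on contrast-stretched
## 8-bit copies of the 16-bit frames, describing them with binary
## intensity-comparison descriptors, matching by Hamming distance, and
## fitting a planar homography robustly. At least 4 point matches are
## required; with fewer, or when the robust fit fails, registration is
## reported absent and the caller is expected to reset its accumulator.

## Fixed binary-descriptor sampling pattern: n_bits pairs of offsets drawn
## once from an isotropic Gaussian inside a patch of the given radius.
brief_pattern <- function(n_bits = 256, radius = 15) {
  local_seed(60932, {
    p <- matrix(stats::rnorm(n_bits * 4, sd = radius / 2.5), ncol = 4)
    matrix(as.integer(round(clamp(p, -radius, radius))), ncol = 4)
  })
}
.brief <- new.env()

## Gaussian blur returning a plain matrix (EBImage returns an Image).
gblur_mat <- function(m, sigma) {
  r <- EBImage::gblur(m, sigma = sigma)
  matrix(as.numeric(r), nrow(m), ncol(m))
}

## Percentile contrast stretch of a raw-count frame to [0, 1]; binary
## descriptors assume a well-spread 8-bit-like intensity range.
stretch_frame <- function(frame, probs = c(0.01, 0.99)) {
  q <- stats::quantile(frame, probs, names = FALSE)
  if (q[2] <= q[1]) return(matrix(0, nrow(frame), ncol(frame)))
  clamp01((frame - q[1]) / (q[2] - q[1]))
}

## Harris corner detection on a [0,1] image. Returns up to n keypoints as a
## data frame (x, y 0-based, response), strongest first, excluding a border
## margin wide enough for descriptor patches.
harris_keypoints <- function(img, n = 500, sigma = 1.5, k = 0.04,
                             border = 18) {
  h <- nrow(img); w <- ncol(img)
  if (h < 2 * border + 5 || w < 2 * border + 5)
    return(data.frame(x = numeric(), y = numeric(), response = numeric()))
  gx <- img; gy <- img
  gx[, 2:(w - 1)] <- (img[, 3:w] - img[, 1:(w - 2)]) / 2
  gy[2:(h - 1), ] <- (img[3:h, ] - img[1:(h - 2), ]) / 2
  gx[, c(1, w)] <- 0; gy[c(1, h), ] <- 0
  sxx <- gblur_mat(gx * gx, sigma)
  syy <- gblur_mat(gy * gy, sigma)
  sxy <- gblur_mat(gx * gy, sigma)
  resp <- (sxx * syy - sxy^2) - k * (sxx + syy)^2
  ## 3x3 non-maximum suppression by shift-compare
  nm <- matrix(TRUE, h, w)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    shifted <- matrix(-Inf, h, w)
    r_dst <- max(1, 1 + dr):min(h, h + dr)
    c_dst <- max(1, 1 + dc):min(w, w + dc)
    shifted[r_dst, c_dst] <- resp[r_dst - dr, c_dst - dc]
    nm <- nm & (resp >= shifted)
  }
  cand <- matrix(FALSE, h, w)
  cand[(border + 1):(h - border), (border + 1):(w - border)] <- TRUE
  cut <- max(resp) * 1e-4
  idx <- which(nm & cand & resp > cut)
  if (!length(idx))
    return(data.frame(x = numeric(), y = numeric(), response = numeric()))
  ord <- order(resp[idx], decreasing = TRUE)
  idx <- idx[ord[seq_len(min(n, length(ord)))]]
  r0 <- ((idx - 1) %% h) + 1L
  c0 <- ((idx - 1) %/% h) + 1L
  ## subpixel peak by 1-D quadratic interpolation of the response
  refine <- function(vm, v0, vp) {
    den <- vm - 2 * v0 + vp
    d <- ifelse(den < 0, 0.5 * (vm - vp) / den, 0)
    clamp(d, -0.5, 0.5)
  }
  dx <- refine(resp[cbind(r0, c0 - 1L)], resp[cbind(r0, c0)],
               resp[cbind(r0, c0 + 1L)])
  dy <- refine(resp[cbind(r0 - 1L, c0)], resp[cbind(r0, c0)],
               resp[cbind(r0 + 1L, c0)])
  data.frame(x = (c0 - 1) + dx, y = (r0 - 1) + dy,
             response = resp[idx])
}

## Binary descriptors: for each keypoint, n_bits comparisons of smoothed
## intensities at fixed offset pairs. Returns a 0/1 matrix (n_kp x n_bits).
binary_descriptors <- function(img, kps, smooth_sigma = 2) {
  if (is.null(.brief$pattern)) .brief$pattern <- brief_pattern()
  pat <- .brief$pattern
  if (!nrow(kps)) return(matrix(0, 0, nrow(pat)))
  sm <- gblur_mat(img, smooth_sigma)
  ky <- round(kps$y); kx <- round(kps$x)   # descriptors sample on the grid
  r1 <- outer(ky, pat[, 2], "+") + 1L
  c1 <- outer(kx, pat[, 1], "+") + 1L
  r2 <- outer(ky, pat[, 4], "+") + 1L
  c2 <- outer(kx, pat[, 3], "+") + 1L
  v1 <- matrix(sm[cbind(as.vector(r1), as.vector(c1))], nrow(kps))
  v2 <- matrix(sm[cbind(as.vector(r2), as.vector(c2))], nrow(kps))
  (v1 < v2) + 0L
}

## Mutual-nearest-neighbour Hamming matching between descriptor sets.
match_descriptors <- function(d1, d2, max_dist = 80) {
  if (!nrow(d1) || !nrow(d2)) return(cbind(i = integer(), j = integer()))
  ## Hamming(a, b) = a %*% (1-b)' + (1-a) %*% b'
  D <- d1 %*% t(1 - d2) + (1 - d1) %*% t(d2)
  j_best <- max.col(-D, ties.method = "first")
  i_best <- max.col(-t(D), ties.method = "first")
  i <- seq_len(nrow(d1))
  mutual <- i_best[j_best] == i
  dist_ok <- D[cbind(i, j_best)] <= max_dist
  keep <- mutual & dist_ok
  cbind(i = i[keep], j = j_best[keep])
}

## Direct linear transform homography fit with Hartley normalization.
fit_homography_dlt <- function(src, dst) {
  norm_pts <- function(p) {
    ctr <- colMeans(p)
    d <- sqrt(rowSums(sweep(p, 2, ctr)^2))
    s <- if (mean(d) > 1e-12) sqrt(2) / mean(d) else 1
    T <- matrix(c(s, 0, 0, 0, s, 0, -s * ctr[1], -s * ctr[2], 1), 3, 3)
    list(T = T, p = cbind(p, 1) %*% t(T))
  }
  ns <- norm_pts(src); nd <- norm_pts(dst)
  n <- nrow(src)
  A <- matrix(0, 2 * n, 9)
  for (i in seq_len(n)) {
    X <- ns$p[i, ]; x <- nd$p[i, 1]; y <- nd$p[i, 2]
    A[2 * i - 1, ] <- c(-X, 0, 0, 0, x * X)
    A[2 * i, ]     <- c(0, 0, 0, -X, y * X)
  }
  hvec <- svd(A, nu = 0, nv = 9)$v[, 9]
  H <- solve(nd$T) %*% matrix(hvec, 3, 3, byrow = TRUE) %*% ns$T
  if (abs(H[3, 3]) < 1e-12 || !is.finite(det(H)) || abs(det(H)) < 1e-12)
    return(NULL)
  homography(H)
}

reprojection_errors <- function(h, src, dst) {
  p <- apply_homography(h, src)
  sqrt(rowSums((p - dst)^2))
}

## RANSAC homography between matched point sets.
ransac_homography <- function(src, dst, thresh = 3, max_iter = 500) {
  n <- nrow(src)
  if (n < 4) return(NULL)
  if (n == 4) {
    h <- fit_homography_dlt(src, dst)
    if (is.null(h)) return(NULL)
    return(list(h = h, inliers = seq_len(4),
                err = mean(reprojection_errors(h, src, dst))))
  }
  best <- NULL; best_n <- 3
  needed <- max_iter
  for (it in seq_len(max_iter)) {
    if (it > needed) break
    s <- sample.int(n, 4)
    h <- tryCatch(fit_homography_dlt(src[s, , drop = FALSE],
                                     dst[s, , drop = FALSE]),
                  error = function(e) NULL)
    if (is.null(h)) next
    e <- reprojection_errors(h, src, dst)
    inl <- which(e <= thresh)
    if (length(inl) > best_n) {
      best <- h; best_n <- length(inl)
      ## standard adaptive stopping: 99.9% chance of one all-inlier sample
      w <- best_n / n
      needed <- if (w >= 1) it else
        min(max_iter, ceiling(log(0.001) / log(1 - w^4)))
    }
  }
  if (is.null(best)) return(NULL)
  inl <- which(reprojection_errors(best, src, dst) <= thresh)
  if (length(inl) >= 4) {
    h2 <- tryCatch(fit_homography_dlt(src[inl, , drop = FALSE],
                                      dst[inl, , drop = FALSE]),
                   error = function(e) NULL)
    if (!is.null(h2)) {
      e2 <- reprojection_errors(h2, src, dst)
      inl2 <- which(e2 <= thresh)
      if (length(inl2) >= length(inl)) { best <- h2; inl <- inl2 }
    }
  }
  list(h = best, inliers = inl,
       err = mean(reprojection_errors(best, src, dst)[inl]))
}

#' Estimate the homography between consecutive frames
#'
#' Aligns `frame_prev` to `frame_cur` by keypoint matching: Harris corners
#' on percentile contrast-stretched copies of the 16-bit frames, binary
#' intensity-comparison descriptors matched by mutual-nearest Hamming
#' distance, and a RANSAC-robust normalized-DLT homography fit (3 px
#' reprojection gate). At least 4 point matches are required; otherwise the
#' result carries no homography and downstream accumulation must reset.
#'
#' @param frame_prev,frame_cur raw-count matrices of identical shape.
#' @param n_keypoints keypoint budget per frame.
#' @param ransac_thresh RANSAC reprojection threshold, pixels.
#' @param seed RANSAC sampling seed (fixed for deterministic output).
#' @return object of class `registration_result`: list with `homography`
#'   (a [homography()] mapping previous-frame to current-frame pixel
#'   coordinates, or `NULL`), `num_matches`, and `reproj_err` (mean inlier
#'   reprojection error in px, `NA` when absent).
#' @export
estimate_homography <- function(frame_prev, frame_cur, n_keypoints = 500,
                                ransac_thresh = 3, seed = 2203) {
  if (!all(dim(frame_prev) == dim(frame_cur)))
    stop("frames must have identical shape", call. = FALSE)
  match_features(frame_features(frame_prev, n_keypoints),
                 frame_features(frame_cur, n_keypoints),
                 ransac_thresh = ransac_thresh, seed = seed)
}

## Keypoints + descriptors for one frame; cached by streaming callers so
## each frame is only analysed once.
frame_features <- function(frame, n_keypoints = 500) {
  img <- stretch_frame(frame)
  kp <- harris_keypoints(img, n = n_keypoints)
  list(kp = kp, desc = binary_descriptors(img, kp))
}

match_features <- function(fa, fb, ransac_thresh = 3, seed = 2203) {
  ka <- fa$kp; kb <- fb$kp
  m <- match_descriptors(fa$desc, fb$desc)
  res <- list(homography = NULL, num_matches = nrow(m), reproj_err = NA_real_)
  class(res) <- "registration_result"
  if (nrow(m) < 4) return(res)
  src <- as.matrix(ka[m[, "i"], c("x", "y")])
  dst <- as.matrix(kb[m[, "j"], c("x", "y")])
  fit <- local_seed(seed, ransac_homography(src, dst, thresh = ransac_thresh))
  if (is.null(fit) || length(fit$inliers) < 4) return(res)
  res$homography <- fit$h
  res$num_matches <- length(fit$inliers)
  res$reproj_err <- fit$err
  res
}

#' @export
print.registration_result <- function(x, ...) {
  if (is.null(x$homography)) {
    cat("registration: FAILED (", x$num_matches, "matches )\n")
  } else {
    cat(sprintf("registration: %d inlier matches, %.3f px reprojection\n",
                x$num_matches, x$reproj_err))
    cat(sprintf("  translation approx (%.2f, %.2f) px\n",
                x$homography[1, 3], x$homography[2, 3]))
  }
  invisible(x)
}

## Wrap a known homography in a registration_result (used when true
## simulator homographies stand in for estimation).
registration_from_homography <- function(h) {
  res <- list(homography = h, num_matches = NA_integer_, reproj_err = 0)
  class(res) <- "registration_result"
  res
}
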