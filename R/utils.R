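#' @keywords internal
"_PACKAGE"

## Small shared helpers. Conventions used throughout the package:
##  - images are numeric matrices with dim = c(height, width); matrix element
##    [r, c] is the pixel at x = c - 1, y = r - 1 (0-based, x right, y down)
##  - bounding boxes are 0-based half-open: [x0, x1) x [y0, y1)
##  - a frame "shape" is c(height, width)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

clamp01 <- function(x) clamp(x, 0, 1)

#' Round half away from zero
#'
#' Rounds to the nearest integer (or `digits` decimal places) with ties going
#' away from zero, the convention used for all reported percentages. Base
#' [round()] rounds ties to even, which does not reproduce survey-report
#' tables.
#'
#' @param x numeric vector.
#' @param digits decimal places to keep.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

## Evaluate `expr` under a fixed RNG seed without disturbing the caller's
## RNG state.
local_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

## Derive a stream-specific child seed from a base seed; kept below 2^31.
child_seed <- function(seed, stream) {
  (as.numeric(seed) * 48271 + stream * 12345) %% 2147483647
}

stop_if_not_shape <- function(shape) {
  if (length(shape) != 2 || any(!is.finite(shape)) || any(shape < 1))
    stop("shape must be c(height, width) with positive entries", call. = FALSE)
  as.integer(shape)
}

## Write a data frame as CSV with full double precision so that
## write -> read round-trips bit-exactly.
write_csv_exact <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
}

read_csv_plain <- function(path, colClasses = NA) {
  utils::read.csv(path, stringsAsFactors = FALSE, colClasses = colClasses)
}
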