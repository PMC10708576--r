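#' Axis-aligned bounding box
#'
#' Boxes are real-valued `(x, y, w, h)` vectors in 0-based image coordinates:
#' `x` is the left edge, `y` the top edge (y grows downward), `w` and `h` the
#' width and height in pixels. A box covers the half-open pixel region
#' `[x, x + w) x [y, y + h)`, matching MOTChallenge CSV semantics. Boxes stay
#' real-valued throughout the pipeline (Kalman prediction produces sub-pixel
#' boxes); discretisation happens only in [pixel_set()].
#'
#' @param x,y Left and top edge in pixels.
#' @param w,h Width and height in pixels, both `>= 0`.
#' @return A named numeric vector `c(x, y, w, h)`.
#' @examples
#' b <- bbox(10, 20, 30, 40)
#' bbox_center(b)
#' @export
bbox <- function(x, y, w, h) {
  stopifnot(is.finite(x), is.finite(y), is.finite(w), is.finite(h), w >= 0, h >= 0)
  c(x = as.numeric(x), y = as.numeric(y), w = as.numeric(w), h = as.numeric(h))
}

# Coerce a box (vector) or set of boxes (4-col matrix / data.frame with
# x,y,w,h columns) to an n x 4 matrix.
as_box_matrix <- function(b) {
  if (is.data.frame(b)) b <- as.matrix(b[, c("x", "y", "w", "h")])
  if (is.null(dim(b))) b <- matrix(b, ncol = 4, dimnames = list(NULL, c("x", "y", "w", "h")))
  stopifnot(ncol(b) == 4)
  colnames(b) <- c("x", "y", "w", "h")
  b
}

#' Intersection over union of two boxes
#'
#' The overlap similarity used for track-detection association and for
#' metric matching. Degenerate (zero-area) boxes have IoU 0 against
#' anything, so they can never be matched.
#'
#' @param a,b Boxes as produced by [bbox()].
#' @return A scalar in `[0, 1]`.
#' @examples
#' iou(bbox(0, 0, 10, 10), bbox(5, 0, 10, 10)) # 1/3
#' @export
iou <- function(a, b) {
  as.numeric(iou_matrix(matrix(a, ncol = 4), matrix(b, ncol = 4)))
}

#' Pairwise IoU matrix
#'
#' @param A,B Sets of boxes: `n x 4` and `m x 4` matrices (columns
#'   `x, y, w, h`), or data frames with those columns.
#' @return An `n x m` matrix of IoU values.
#' @export
iou_matrix <- function(A, B) {
  A <- as_box_matrix(A)
  B <- as_box_matrix(B)
  n <- nrow(A)
  m <- nrow(B)
  if (n == 0 || m == 0) return(matrix(0, n, m))
  ax1 <- A[, 1]; ay1 <- A[, 2]; ax2 <- A[, 1] + A[, 3]; ay2 <- A[, 2] + A[, 4]
  bx1 <- B[, 1]; by1 <- B[, 2]; bx2 <- B[, 1] + B[, 3]; by2 <- B[, 2] + B[, 4]
  ix <- pmax(outer(ax2, bx2, pmin) - outer(ax1, bx1, pmax), 0)
  iy <- pmax(outer(ay2, by2, pmin) - outer(ay1, by1, pmax), 0)
  inter <- ix * iy
  area_a <- A[, 3] * A[, 4]
  area_b <- B[, 3] * B[, 4]
  un <- outer(area_a, area_b, `+`) - inter
  out <- ifelse(un > 0, inter / un, 0)
  matrix(out, n, m)
}

#' Centre point of a box
#'
#' @param b A box, or an `n x 4` matrix of boxes.
#' @return `c(px, py)` for a single box, or an `n x 2` matrix.
#' @export
bbox_center <- function(b) {
  m <- as_box_matrix(b)
  ctr <- cbind(px = m[, 1] + m[, 3] / 2, py = m[, 2] + m[, 4] / 2)
  if (is.null(dim(b)) && !is.data.frame(b)) ctr[1, ] else ctr
}

#' Clip a box to the frame
#'
#' Intersects `b` with the frame rectangle `[0, width) x [0, height)`. A box
#' fully outside the frame collapses to a zero-area box at the nearest
#' border. Idempotent.
#'
#' @param b A box.
#' @param width,height Frame dimensions in pixels (positive).
#' @return The clipped box.
#' @export
clip_bbox <- function(b, width, height) {
  stopifnot(width > 0, height > 0)
  x1 <- min(max(b[[1]], 0), width)
  y1 <- min(max(b[[2]], 0), height)
  x2 <- min(max(b[[1]] + b[[3]], 0), width)
  y2 <- min(max(b[[2]] + b[[4]], 0), height)
  bbox(x1, y1, max(x2 - x1, 0), max(y2 - y1, 0))
}

#' Integer pixel positions covered by a box
#'
#' Discretises a (clipped) box onto the pixel grid: edges are rounded to the
#' nearest grid line and every pixel whose centre falls inside the rounded
#' box is returned. This is the pixel set `B` over which mean in-box flow
#' magnitude is averaged.
#'
#' @param b A box.
#' @param width,height Frame dimensions in pixels.
#' @return An integer matrix with columns `u, v` (0-based pixel coordinates);
#'   zero rows for a zero-area box.
#' @export
pixel_set <- function(b, width, height) {
  cb <- clip_bbox(b, width, height)
  # floor(x + 0.5): conventional half-up rounding, not banker's rounding
  x1 <- floor(cb[[1]] + 0.5)
  y1 <- floor(cb[[2]] + 0.5)
  x2 <- floor(cb[[1]] + cb[[3]] + 0.5)
  y2 <- floor(cb[[2]] + cb[[4]] + 0.5)
  x2 <- min(x2, width)
  y2 <- min(y2, height)
  if (x2 <= x1 || y2 <= y1) {
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("u", "v"))))
  }
  us <- seq.int(x1, x2 - 1L)
  vs <- seq.int(y1, y2 - 1L)
  cbind(u = rep(as.integer(us), times = length(vs)),
        v = rep(as.integer(vs), each = length(us)))
}
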