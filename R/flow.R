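# Dense optical flow under the brightness constancy model
# I(x, y, t) = I(x + dx, y + dy, t + 1): the flow field F assigns every
# pixel of frame t its displacement (dx, dy), in pixels/frame, toward
# frame t+1 (forward flow). The built-in estimator is a coarse-to-fine
# pyramidal least-squares (Lucas-Kanade) scheme with Gaussian-weighted
# windows, iterative warping, and a 3x3 median cleanup per pyramid level.
# Any other provider (e.g. precomputed Middlebury .flo files) can stand in
# downstream: all consumers only see flow_field objects.

#' Dense flow field
#'
#' @param du,dv `H x W` matrices of per-pixel displacements along x and y
#'   (pixels/frame), same orientation as image matrices (rows = y).
#' @return A `flow_field` with elements `du`, `dv`, `height`, `width`.
#' @export
flow_field <- function(du, dv) {
  stopifnot(is.matrix(du), is.matrix(dv), all(dim(du) == dim(dv)),
            all(is.finite(du)), all(is.finite(dv)))
  structure(list(du = du, dv = dv, height = nrow(du), width = ncol(du)),
            class = "flow_field")
}

#' @export
print.flow_field <- function(x, ...) {
  mag <- sqrt(x$du^2 + x$dv^2)
  cat(sprintf("flow_field %d x %d px; |F|: median %.3f, max %.3f px/frame\n",
              x$width, x$height, stats::median(mag), max(mag)))
  invisible(x)
}

#' Flow estimator configuration
#'
#' @param pyramid_levels Number of pyramid levels (>= 1).
#' @param pyramid_scale Downscaling ratio between levels, in (0, 1).
#' @param window Side of the weighted least-squares window (odd, >= 3).
#' @param iterations Warp-and-refine iterations per level.
#' @return A `flow_config` list.
#' @export
flow_config <- function(pyramid_levels = 3L, pyramid_scale = 0.5,
                        window = 15L, iterations = 3L) {
  stopifnot(pyramid_levels >= 1, pyramid_scale > 0, pyramid_scale < 1,
            window >= 3, window %% 2 == 1, iterations >= 1)
  structure(list(pyramid_levels = as.integer(pyramid_levels),
                 pyramid_scale = pyramid_scale,
                 window = as.integer(window),
                 iterations = as.integer(iterations)),
            class = "flow_config")
}

to_gray <- function(img) {
  if (length(dim(img)) == 3) {
    # luminance as the plain channel average
    img <- apply(img, c(1, 2), mean)
  }
  stopifnot(is.matrix(img))
  img
}

# One weighted-least-squares refinement pass at a single scale: warp I2 by
# the current estimate, accumulate Gaussian-weighted structure sums of the
# brightness-constancy normal equations, solve the per-pixel 2x2 system.
lk_refine <- function(I1, I2, du, dv, window, gk) {
  h <- nrow(I1)
  w <- ncol(I1)
  gx <- rep(seq_len(w) - 1, each = h)
  gy <- rep(seq_len(h) - 1, times = w)
  warped <- matrix(interp2(I2, gx + as.vector(du), gy + as.vector(dv)), h, w)
  avg <- (I1 + warped) / 2
  # central-difference gradients, replicate borders
  lf <- c(1L, seq_len(w - 1L)); rt <- c(seq_len(w - 1L) + 1L, w)
  up <- c(1L, seq_len(h - 1L)); dn <- c(seq_len(h - 1L) + 1L, h)
  Ix <- (avg[, rt] - avg[, lf]) / 2
  Iy <- (avg[dn, ] - avg[up, ]) / 2
  It <- warped - I1
  wsum <- function(m) conv_sep(m, gk)
  Sxx <- wsum(Ix * Ix)
  Sxy <- wsum(Ix * Iy)
  Syy <- wsum(Iy * Iy)
  Sxt <- wsum(Ix * It)
  Syt <- wsum(Iy * It)
  det <- Sxx * Syy - Sxy^2
  ok <- det > 1e-9 & (Sxx + Syy) > 1e-7
  inc_u <- ifelse(ok, (Sxy * Syt - Syy * Sxt) / det, 0)
  inc_v <- ifelse(ok, (Sxy * Sxt - Sxx * Syt) / det, 0)
  # guard against blow-ups where the normal equations are ill-conditioned
  lim <- window
  inc_u <- pmin(pmax(inc_u, -lim), lim)
  inc_v <- pmin(pmax(inc_v, -lim), lim)
  list(du = du + inc_u, dv = dv + inc_v)
}

#' Estimate dense optical flow between two frames
#'
#' Coarse-to-fine pyramidal least-squares estimation of the forward flow
#' from `frame_t` to `frame_t1`. Colour inputs (H x W x 3 arrays) are
#' converted to grayscale by channel averaging. Textureless regions where
#' the normal equations degenerate yield zero flow rather than noise; flow
#' near the frame border (within about one window) is inherently less
#' reliable than in the interior.
#'
#' @param frame_t,frame_t1 Images as numeric matrices (or H x W x 3
#'   arrays), identical dimensions.
#' @param config A [flow_config()].
#' @return A [flow_field()] of the same height and width as the frames.
#' @export
estimate_flow <- function(frame_t, frame_t1, config = flow_config()) {
  I1 <- to_gray(frame_t)
  I2 <- to_gray(frame_t1)
  if (!all(dim(I1) == dim(I2))) stop("estimate_flow: frame dimensions differ")
  scale <- config$pyramid_scale
  gk <- gaussian_kernel(config$window / 4)
  blur <- gaussian_kernel(0.5 / scale)
  # build pyramids, dropping levels that would undercut the window size
  p1 <- list(I1)
  p2 <- list(I2)
  for (l in seq_len(config$pyramid_levels - 1L)) {
    prev1 <- p1[[l]]
    nh <- max(round(nrow(prev1) * scale), 4L)
    nw <- max(round(ncol(prev1) * scale), 4L)
    if (min(nh, nw) < config$window) break
    p1[[l + 1L]] <- resize_bilinear(conv_sep(p1[[l]], blur), nh, nw)
    p2[[l + 1L]] <- resize_bilinear(conv_sep(p2[[l]], blur), nh, nw)
  }
  nl <- length(p1)
  du <- matrix(0, nrow(p1[[nl]]), ncol(p1[[nl]]))
  dv <- matrix(0, nrow(p1[[nl]]), ncol(p1[[nl]]))
  for (l in rev(seq_len(nl))) {
    if (l < nl) {
      fac_h <- nrow(p1[[l]]) / nrow(p1[[l + 1L]])
      fac_w <- ncol(p1[[l]]) / ncol(p1[[l + 1L]])
      du <- resize_bilinear(du, nrow(p1[[l]]), ncol(p1[[l]])) * fac_w
      dv <- resize_bilinear(dv, nrow(p1[[l]]), ncol(p1[[l]])) * fac_h
    }
    for (it in seq_len(config$iterations)) {
      res <- lk_refine(p1[[l]], p2[[l]], du, dv, config$window, gk)
      du <- res$du
      dv <- res$dv
    }
    du <- median3x3(du)
    dv <- median3x3(dv)
  }
  flow_field(du, dv)
}

#' Sample a flow field at a sub-pixel point
#'
#' Bilinear interpolation of the stored per-pixel displacements; exact at
#' integer grid nodes.
#'
#' @param F A [flow_field()].
#' @param p Point `c(px, py)` with `0 <= px <= W-1`, `0 <= py <= H-1`.
#' @return `c(dx, dy)`.
#' @export
flow_at <- function(F, p) {
  px <- p[[1]]
  py <- p[[2]]
  if (!is.finite(px) || !is.finite(py) ||
      px < 0 || px > F$width - 1 || py < 0 || py > F$height - 1) {
    stop("flow_at: point (", px, ", ", py, ") outside the field")
  }
  c(dx = interp2(F$du, px, py), dy = interp2(F$dv, px, py))
}

.flo_magic <- 202021.25

#' Read a Middlebury .flo file
#'
#' Layout: float32 magic `202021.25`, int32 width, int32 height, then
#' row-major interleaved float32 `(dx, dy)` pairs.
#'
#' @param path Path to a `.flo` file.
#' @return A [flow_field()].
#' @export
read_flo <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "numeric", n = 1, size = 4, endian = "little")
  if (length(magic) == 0 || abs(magic - .flo_magic) > 1e-3) {
    stop("read_flo: '", path, "' is not a .flo file (bad magic)")
  }
  dims <- readBin(con, "integer", n = 2, size = 4, endian = "little")
  if (length(dims) < 2 || any(dims <= 0) || any(dims > 1e5)) {
    stop("read_flo: '", path, "' has invalid dimensions")
  }
  w <- dims[1]
  h <- dims[2]
  vals <- readBin(con, "numeric", n = 2 * w * h, size = 4, endian = "little")
  if (length(vals) != 2 * w * h) stop("read_flo: '", path, "' is truncated")
  du <- matrix(vals[seq(1, length(vals), by = 2)], nrow = h, ncol = w, byrow = TRUE)
  dv <- matrix(vals[seq(2, length(vals), by = 2)], nrow = h, ncol = w, byrow = TRUE)
  flow_field(du, dv)
}

#' Write a Middlebury .flo file
#'
#' Values are stored as float32; a write/read cycle is bit-exact for values
#' already representable in single precision.
#'
#' @param F A [flow_field()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_flo <- function(F, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(.flo_magic, con, size = 4, endian = "little")
  writeBin(as.integer(c(F$width, F$height)), con, size = 4, endian = "little")
  inter <- as.vector(rbind(as.vector(t(F$du)), as.vector(t(F$dv))))
  writeBin(inter, con, size = 4, endian = "little")
  invisible(path)
}
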