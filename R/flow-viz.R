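# Flow visualisation: the dense colour coding (hue = direction, colour
# intensity = magnitude, zero flow = white) and the sparse arrow plot
# (one arrow per grid cell, direction and length from the sampled flow).

# vectorised HSV -> RGB on equal-shape matrices, h in [0,1)
hsv_to_rgb <- function(h, s, v) {
  h6 <- (h * 6) %% 6
  i <- floor(h6)
  f <- h6 - i
  p <- v * (1 - s)
  q <- v * (1 - f * s)
  t <- v * (1 - (1 - f) * s)
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  list(r = r, g = g, b = b)
}

#' Dense flow colour image
#'
#' Encodes flow direction as hue and magnitude as colour saturation
#' (normalised by the field's maximum magnitude, or by `max_mag` when
#' frame-to-frame comparability is wanted). Zero flow maps to white.
#'
#' @param F A [flow_field()].
#' @param max_mag Optional absolute magnitude cap used for normalisation.
#' @return An `H x W x 3` RGB array in `[0, 1]`.
#' @export
flow_to_color <- function(F, max_mag = NULL) {
  mag <- sqrt(F$du^2 + F$dv^2)
  if (is.null(max_mag)) max_mag <- max(mag)
  if (max_mag <= 0) max_mag <- 1
  hue <- (atan2(F$dv, F$du) / (2 * pi)) %% 1
  sat <- pmin(mag / max_mag, 1)
  rgb <- hsv_to_rgb(hue, sat, matrix(1, F$height, F$width))
  out <- array(0, dim = c(F$height, F$width, 3))
  out[, , 1] <- rgb$r
  out[, , 2] <- rgb$g
  out[, , 3] <- rgb$b
  out
}

#' Sparse arrow sampling of a flow field
#'
#' Samples one arrow per `stride x stride` cell, anchored at the cell
#' centre, with components equal to the (bilinearly sampled) flow there.
#' This is the data behind the sparse arrow visualisation; use
#' [plot_flow_arrows()] to render it.
#'
#' @param F A [flow_field()].
#' @param stride Cell side in pixels (>= 1).
#' @return Data frame `x, y, dx, dy, mag`, one row per cell
#'   (`ceiling(H/stride) * ceiling(W/stride)` rows).
#' @export
flow_arrows <- function(F, stride = 16) {
  stopifnot(stride >= 1)
  cx <- (seq_len(ceiling(F$width / stride)) - 0.5) * stride
  cy <- (seq_len(ceiling(F$height / stride)) - 0.5) * stride
  cx <- pmin(cx, F$width - 1)
  cy <- pmin(cy, F$height - 1)
  grid <- expand.grid(x = cx, y = cy)
  dx <- interp2(F$du, grid$x, grid$y)
  dy <- interp2(F$dv, grid$x, grid$y)
  data.frame(x = grid$x, y = grid$y, dx = dx, dy = dy,
             mag = sqrt(dx^2 + dy^2))
}

#' Render the sparse arrow visualisation
#'
#' Draws the base image (if any) with one arrow per grid cell; arrow
#' direction gives the motion direction and length the magnitude
#' (`scale` pixels of arrow per pixel of flow).
#'
#' @param F A [flow_field()].
#' @param base_image Optional background image (matrix or RGB array).
#' @param stride Grid cell side in pixels.
#' @param scale Arrow length multiplier.
#' @param file Optional PNG path; when given, rendering goes to that file.
#' @return The arrow data frame from [flow_arrows()], invisibly.
#' @export
plot_flow_arrows <- function(F, base_image = NULL, stride = 16, scale = 1,
                             file = NULL) {
  arr <- flow_arrows(F, stride)
  if (!is.null(file)) {
    grDevices::png(file, width = F$width, height = F$height)
    on.exit(grDevices::dev.off())
    graphics::par(mar = c(0, 0, 0, 0))
  }
  plot(NA, xlim = c(0, F$width), ylim = c(F$height, 0), asp = 1,
       xlab = "", ylab = "", axes = is.null(file))
  if (!is.null(base_image)) {
    graphics::rasterImage(grDevices::as.raster(base_image), 0, F$height, F$width, 0)
  }
  graphics::points(arr$x, arr$y, col = "red", pch = 16, cex = 0.4)
  # arrows below half a pixel of rendered length are visual noise
  moving <- scale * arr$mag > 0.5
  if (any(moving)) {
    suppressWarnings(
      graphics::arrows(arr$x[moving], arr$y[moving],
                       arr$x[moving] + scale * arr$dx[moving],
                       arr$y[moving] + scale * arr$dy[moving],
                       length = 0.04, col = "green3"))
  }
  invisible(arr)
}

#' Overlay tracked boxes and identities on a frame
#'
#' @param frame Image matrix (grayscale) or RGB array.
#' @param boxes Data frame with columns `id, x, y, w, h` for one frame.
#' @param file Optional PNG output path.
#' @return `boxes`, invisibly.
#' @export
plot_track_overlay <- function(frame, boxes, file = NULL) {
  h <- dim(frame)[1]
  w <- dim(frame)[2]
  if (!is.null(file)) {
    grDevices::png(file, width = w, height = h)
    on.exit(grDevices::dev.off())
    graphics::par(mar = c(0, 0, 0, 0))
  }
  plot(NA, xlim = c(0, w), ylim = c(h, 0), asp = 1, xlab = "", ylab = "",
       axes = is.null(file))
  graphics::rasterImage(grDevices::as.raster(frame), 0, h, w, 0)
  if (nrow(boxes) > 0) {
    cols <- grDevices::hcl.colors(max(boxes$id, 3), "Dark 3")
    graphics::rect(boxes$x, boxes$y + boxes$h, boxes$x + boxes$w, boxes$y,
                   border = cols[boxes$id], lwd = 2)
    graphics::text(boxes$x + 4, boxes$y + 10, labels = boxes$id,
                   col = cols[boxes$id], font = 2)
  }
  invisible(boxes)
}

#' Plot per-frame or cumulative movement curves
#'
#' One line per track identity, frames on the x axis.
#'
#' @param series Movement series from [per_track_movement()].
#' @param cumulative Plot the running sums instead of per-frame values.
#' @param file Optional PNG output path.
#' @return The series, invisibly.
#' @export
plot_movement <- function(series, cumulative = FALSE, file = NULL) {
  if (!is.null(file)) {
    grDevices::png(file, width = 720, height = 480)
    on.exit(grDevices::dev.off())
  }
  ycol <- if (cumulative) "cumulative_px" else "movement_px"
  ids <- sort(unique(series$track_id))
  cols <- grDevices::hcl.colors(max(length(ids), 3), "Dark 3")
  plot(NA, xlim = range(series$frame), ylim = c(0, max(series[[ycol]], 1)),
       xlab = "frame", ylab = if (cumulative) "cumulative movement (px)" else
         "movement (px/frame)",
       main = unique(series$method)[1])
  for (k in seq_along(ids)) {
    s <- series[series$track_id == ids[k], ]
    graphics::lines(s$frame, s[[ycol]], col = cols[k], lwd = 2)
  }
  graphics::legend("topleft", legend = paste("id", ids), col = cols[seq_along(ids)],
                   lwd = 2, bty = "n", cex = 0.8)
  invisible(series)
}
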