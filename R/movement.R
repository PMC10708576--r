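# Per-animal movement estimators. Movement between frames t and t+1 is a
# non-negative scalar in pixels, computed either from bounding boxes alone
# (centre displacement) or from the dense flow field of the frame pair
# (representative-point flow, or mean in-box flow magnitude — the default,
# since it integrates motion of every body part and is immune to box-size
# fluctuation around stationary animals).

#' Centre-displacement movement
#'
#' Euclidean distance between the centres of a track's boxes in two
#' consecutive frames. Simple, but any detection-box jitter around a
#' stationary animal registers as spurious movement.
#'
#' @param box_t,box_t1 The track's boxes at frames `t` and `t + 1`.
#' @return Movement in pixels.
#' @export
bbox_center_movement <- function(box_t, box_t1) {
  c0 <- bbox_center(box_t)
  c1 <- bbox_center(box_t1)
  sqrt(sum((c1 - c0)^2))
}

#' Representative-point movement
#'
#' Magnitude of the flow vector at a representative point (the track's
#' initial box centre, advanced frame to frame by [propagate_point()]).
#'
#' @param F A [flow_field()].
#' @param p Point `c(px, py)` inside the field.
#' @return Movement in pixels.
#' @export
rep_point_movement <- function(F, p) {
  v <- flow_at(F, p)
  sqrt(sum(v^2))
}

#' Advance a point by the flow field
#'
#' Returns `p + F(p)`, clipped to the field bounds, giving the
#' representative point's position in the next frame.
#'
#' @param p Point `c(px, py)` inside the field.
#' @param F A [flow_field()].
#' @return The propagated point.
#' @export
propagate_point <- function(p, F) {
  v <- flow_at(F, p)
  q <- c(p[[1]] + v[[1]], p[[2]] + v[[2]])
  c(px = min(max(q[1], 0), F$width - 1), py = min(max(q[2], 0), F$height - 1))
}

#' Mean in-box flow movement
#'
#' Averages the per-pixel flow magnitude over the pixel set of the box
#' (clipped to the frame): `M = (1/|B|) * sum_{(u,v) in B} ||F(u,v)||`.
#' For a partially out-of-frame box the average runs over the visible
#' pixels only. Note the average includes background pixels inside the
#' box, so an object covering fraction `f` of its box moving at speed `s`
#' over still background yields `f * s` (the fill-factor effect).
#'
#' @param F A [flow_field()].
#' @param box A box overlapping the frame.
#' @return Movement in pixels.
#' @export
box_mean_flow_movement <- function(F, box) {
  px <- pixel_set(box, F$width, F$height)
  if (nrow(px) == 0) stop("box_mean_flow_movement: box covers no pixels of the frame")
  idx <- cbind(px[, 2] + 1L, px[, 1] + 1L)
  mean(sqrt(F$du[idx]^2 + F$dv[idx]^2))
}

track_table <- function(tracks) {
  if (is.data.frame(tracks)) {
    stopifnot(all(c("frame", "id", "x", "y", "w", "h") %in% names(tracks)))
    tracks
  } else {
    tracks_to_table(tracks)
  }
}

#' Per-track movement series
#'
#' Computes one movement value per track per consecutive frame pair the
#' track covers, by the chosen estimator, plus running cumulative sums.
#' The box used for pair `(t, t + 1)` is the track's box at frame `t`
#' (forward flow is anchored at frame `t`). Frames where a track is absent
#' (lost) contribute no records; the cumulative sum simply carries across
#' the gap.
#'
#' @param tracks Track list from [track_sequence()] or a table with columns
#'   `frame, id, x, y, w, h`.
#' @param flows Named list of [flow_field()]s: element `"t"` holds the flow
#'   from frame `t` to `t + 1`. May be `NULL` for `method = "bbox_center"`.
#' @param method One of `"box_mean_flow"` (default), `"bbox_center"`,
#'   `"rep_point"`.
#' @return A movement series: data frame with columns
#'   `track_id, frame, method, movement_px, cumulative_px`, ordered by
#'   `(track_id, frame)`; `frame` is the first frame of the pair.
#' @export
per_track_movement <- function(tracks, flows = NULL,
                               method = c("box_mean_flow", "bbox_center", "rep_point")) {
  method <- match.arg(method)
  tab <- track_table(tracks)
  out <- list()
  for (id in sort(unique(tab$id))) {
    tt <- tab[tab$id == id, , drop = FALSE]
    tt <- tt[order(tt$frame), , drop = FALSE]
    pair_idx <- which((tt$frame + 1L) %in% tt$frame)
    rep_pt <- bbox_center(bbox(tt$x[1], tt$y[1], tt$w[1], tt$h[1]))
    vals <- numeric(0)
    frames <- integer(0)
    for (k in pair_idx) {
      f <- tt$frame[k]
      box_t <- bbox(tt$x[k], tt$y[k], tt$w[k], tt$h[k])
      if (method == "bbox_center") {
        k1 <- which(tt$frame == f + 1L)
        box_t1 <- bbox(tt$x[k1], tt$y[k1], tt$w[k1], tt$h[k1])
        v <- bbox_center_movement(box_t, box_t1)
      } else {
        Ff <- flows[[as.character(f)]]
        if (is.null(Ff)) stop("per_track_movement: no flow field for frame pair (",
                              f, ", ", f + 1L, ")")
        if (method == "rep_point") {
          v <- rep_point_movement(Ff, rep_pt)
          rep_pt <- propagate_point(rep_pt, Ff)
        } else {
          v <- box_mean_flow_movement(Ff, box_t)
        }
      }
      vals <- c(vals, v)
      frames <- c(frames, f)
    }
    if (length(vals) > 0) {
      out[[length(out) + 1L]] <- data.frame(
        track_id = id, frame = frames, method = method,
        movement_px = vals, cumulative_px = cumsum(vals))
    }
  }
  if (length(out) == 0) {
    return(data.frame(track_id = integer(0), frame = integer(0),
                      method = character(0), movement_px = numeric(0),
                      cumulative_px = numeric(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Recompute cumulative movement
#'
#' Rebuilds the per-track running sums of a movement series (records must
#' be ordered by frame within track).
#'
#' @param series A movement series data frame.
#' @return The series with `cumulative_px` recomputed.
#' @export
cumulative_movement <- function(series) {
  if (nrow(series) == 0) return(series)
  series$cumulative_px <- stats::ave(series$movement_px, series$track_id, FUN = cumsum)
  series
}
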