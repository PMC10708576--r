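#' Tracker configuration
#'
#' Parameters of the two-stage association tracker. `tau` splits detections
#' into high- and low-confidence sets; high-confidence detections are
#' associated with predicted track boxes first, and low-confidence ones
#' (typically partially occluded animals) get a second chance against the
#' tracks left unmatched. Defaults follow the reported pig-pen settings:
#' detection threshold 0.1, NMS and matching thresholds 0.5, lost tracks
#' retained 30 frames, at most 100 retained tracks.
#'
#' @param tau Score threshold splitting high/low confidence detections.
#' @param det_thresh Minimum detection score kept at all.
#' @param match_thresh_high Minimum IoU accepted in the first association.
#' @param match_thresh_low Minimum IoU accepted in the second association.
#' @param max_lost_frames Frames a lost track is retained before removal.
#' @param max_tracks Cap on simultaneously retained (non-removed) tracks.
#' @param nms_thresh IoU threshold of the greedy NMS applied to incoming
#'   detections before splitting.
#' @return A `tracker_config` list.
#' @export
tracker_config <- function(tau = 0.5, det_thresh = 0.1,
                           match_thresh_high = 0.5, match_thresh_low = 0.5,
                           max_lost_frames = 30L, max_tracks = 100L,
                           nms_thresh = 0.5) {
  stopifnot(det_thresh >= 0, det_thresh <= tau, tau <= 1,
            match_thresh_high >= 0, match_thresh_high <= 1,
            match_thresh_low >= 0, match_thresh_low <= 1,
            nms_thresh >= 0, nms_thresh <= 1,
            max_lost_frames >= 0, max_tracks >= 1)
  structure(list(tau = tau, det_thresh = det_thresh,
                 match_thresh_high = match_thresh_high,
                 match_thresh_low = match_thresh_low,
                 max_lost_frames = as.integer(max_lost_frames),
                 max_tracks = as.integer(max_tracks),
                 nms_thresh = nms_thresh),
            class = "tracker_config")
}

#' Scored detections table
#'
#' Detections are a data frame with columns `frame` (0-based integer),
#' `x, y, w, h` (pixels) and `score` in `[0, 1]`.
#'
#' @param frame Integer frame indices (0-based).
#' @param x,y,w,h Box coordinates.
#' @param score Confidence scores in `[0, 1]`.
#' @return A detections data frame.
#' @export
detections <- function(frame, x, y, w, h, score) {
  stopifnot(all(score >= 0 & score <= 1), all(w >= 0), all(h >= 0))
  data.frame(frame = as.integer(frame), x = as.numeric(x), y = as.numeric(y),
             w = as.numeric(w), h = as.numeric(h), score = as.numeric(score))
}

#' Greedy non-maximum suppression
#'
#' Per frame, keeps detections in descending score order, discarding any
#' detection whose IoU with an already kept one exceeds `thresh`.
#' Ties in score are broken by original row order.
#'
#' @param dets Detections data frame.
#' @param thresh IoU suppression threshold.
#' @return The surviving detections, original order preserved.
#' @export
nms_detections <- function(dets, thresh = 0.5) {
  if (nrow(dets) == 0) return(dets)
  keep_all <- logical(nrow(dets))
  for (f in unique(dets$frame)) {
    idx <- which(dets$frame == f)
    ord <- idx[order(-dets$score[idx], seq_along(idx))]
    boxes <- as_box_matrix(dets[ord, ])
    kept <- integer(0)
    for (i in seq_along(ord)) {
      if (length(kept) == 0 ||
          all(iou_matrix(boxes[i, , drop = FALSE], boxes[kept, , drop = FALSE]) <= thresh)) {
        kept <- c(kept, i)
      }
    }
    keep_all[ord[kept]] <- TRUE
  }
  dets[keep_all, , drop = FALSE]
}

#' Split one frame's detections by confidence
#'
#' Detections scoring below `det_thresh` are discarded; the remainder go to
#' the high set if `score > tau`, otherwise to the low set. Order preserved.
#'
#' @param dets Detections of a single frame.
#' @param config A [tracker_config()].
#' @return `list(high = ..., low = ...)` of detections data frames.
#' @export
split_detections <- function(dets, config = tracker_config()) {
  if (nrow(dets) > 0 && length(unique(dets$frame)) > 1) {
    stop("split_detections: detections must come from a single frame")
  }
  kept <- dets[dets$score >= config$det_thresh, , drop = FALSE]
  list(high = kept[kept$score > config$tau, , drop = FALSE],
       low = kept[kept$score <= config$tau, , drop = FALSE])
}

#' Optimal IoU association
#'
#' Solves the global assignment between predicted track boxes and detection
#' boxes minimising total `1 - IoU` cost (Hungarian method), then demotes
#' any assigned pair whose IoU falls below `iou_gate` to unmatched. Ties
#' between equal-cost assignments are broken lexicographically by
#' (track index, detection index), so association is deterministic.
#'
#' @param pred_boxes `n x 4` matrix of track boxes (or data frame).
#' @param det_boxes `m x 4` matrix of detection boxes.
#' @param iou_gate Minimum IoU for an accepted match.
#' @return `list(matches = k x 2 matrix (track, det), unmatched_tracks,
#'   unmatched_dets)` using 1-based indices.
#' @export
associate <- function(pred_boxes, det_boxes, iou_gate = 0.5) {
  stopifnot(iou_gate >= 0, iou_gate <= 1)
  A <- as_box_matrix(pred_boxes)
  B <- as_box_matrix(det_boxes)
  n <- nrow(A)
  m <- nrow(B)
  empty <- matrix(integer(0), ncol = 2, dimnames = list(NULL, c("track", "det")))
  if (n == 0 || m == 0) {
    return(list(matches = empty, unmatched_tracks = seq_len(n), unmatched_dets = seq_len(m)))
  }
  ious <- iou_matrix(A, B)
  cost <- 1 - ious
  # infinitesimal lexicographic bias: among equal-cost optima prefer the
  # pairing with the smallest (track, det) indices
  eps <- 1e-9 / (n * m + 1)
  bias <- outer(seq_len(n), seq_len(m), function(i, j) (i * (m + 1) + j) * eps)
  cost_b <- cost + bias
  if (n <= m) {
    sol <- clue::solve_LSAP(cost_b)
    assign_det <- as.integer(sol) # per track
  } else {
    sol <- clue::solve_LSAP(t(cost_b))
    assign_det <- rep(NA_integer_, n)
    assign_det[as.integer(sol)] <- seq_len(m)
  }
  pairs <- cbind(track = seq_len(n), det = assign_det)
  pairs <- pairs[!is.na(pairs[, 2]), , drop = FALSE]
  ok <- ious[pairs] >= iou_gate & ious[pairs] > 0
  matches <- pairs[ok, , drop = FALSE]
  if (nrow(matches) == 0) matches <- empty
  list(matches = matches,
       unmatched_tracks = setdiff(seq_len(n), matches[, 1]),
       unmatched_dets = setdiff(seq_len(m), matches[, 2]))
}

new_track <- function(id, box, frame, score) {
  list(track_id = as.integer(id),
       state = kf_initiate(box),
       status = "active",
       frames_since_update = 0L,
       frames = as.integer(frame),
       boxes = matrix(box, ncol = 4, dimnames = list(NULL, c("x", "y", "w", "h"))),
       scores = score)
}

track_record <- function(tr, frame, box, score) {
  tr$frames <- c(tr$frames, as.integer(frame))
  tr$boxes <- rbind(tr$boxes, box)
  tr$scores <- c(tr$scores, score)
  tr
}

#' One frame of two-stage association tracking
#'
#' Executes a single step of the two-stage matching scheme: NMS and
#' confidence split of the frame's detections; Kalman prediction of every
#' retained (active or lost) track; first association of predicted boxes
#' against high-confidence detections; second association of the remaining
#' tracks against low-confidence detections; matched tracks updated and
#' reactivated, unmatched low detections discarded, unmatched tracks marked
#' lost and removed once lost longer than `max_lost_frames`, unmatched
#' high-confidence detections started as new active tracks; finally the
#' retained-track cap is enforced, evicting the longest-lost tracks first.
#'
#' @param tracks List of track objects from the previous frame (may include
#'   removed tracks; they are carried through untouched).
#' @param dets Detections of one frame (all rows share one frame index).
#' @param config A [tracker_config()].
#' @param frame The frame index; defaults to the detections' frame. Required
#'   when `dets` is empty.
#' @return The updated list of tracks (removed tracks included).
#' @export
byte_step <- function(tracks, dets, config = tracker_config(), frame = NULL) {
  if (nrow(dets) > 0) {
    fr <- unique(dets$frame)
    if (length(fr) > 1) stop("byte_step: detections from mixed frames")
    if (!is.null(frame) && frame != fr) stop("byte_step: frame does not match detections")
    frame <- fr
  }
  if (is.null(frame)) stop("byte_step: frame index required when no detections are given")

  dets <- nms_detections(dets, config$nms_thresh)
  sp <- split_detections(dets, config)
  d_high <- sp$high
  d_low <- sp$low

  alive <- which(vapply(tracks, function(t) t$status != "removed", logical(1)))
  for (i in alive) tracks[[i]]$state <- kf_predict(tracks[[i]]$state)
  pred_boxes <- t(vapply(alive, function(i) kf_box(tracks[[i]]$state), numeric(4)))
  if (length(alive) == 0) pred_boxes <- matrix(numeric(0), ncol = 4)

  matched_tracks <- integer(0)

  # first association: all retained tracks vs high-confidence detections
  a1 <- associate(pred_boxes, as_box_matrix(d_high), config$match_thresh_high)
  for (k in seq_len(nrow(a1$matches))) {
    ti <- alive[a1$matches[k, 1]]
    di <- a1$matches[k, 2]
    box <- bbox(d_high$x[di], d_high$y[di], d_high$w[di], d_high$h[di])
    tracks[[ti]]$state <- kf_update(tracks[[ti]]$state, box)
    tracks[[ti]]$status <- "active"
    tracks[[ti]]$frames_since_update <- 0L
    tracks[[ti]] <- track_record(tracks[[ti]], frame, box, d_high$score[di])
    matched_tracks <- c(matched_tracks, ti)
  }

  # second association: remaining tracks vs low-confidence detections
  remain <- alive[a1$unmatched_tracks]
  if (length(remain) > 0 && nrow(d_low) > 0) {
    rb <- t(vapply(remain, function(i) kf_box(tracks[[i]]$state), numeric(4)))
    a2 <- associate(rb, as_box_matrix(d_low), config$match_thresh_low)
    for (k in seq_len(nrow(a2$matches))) {
      ti <- remain[a2$matches[k, 1]]
      di <- a2$matches[k, 2]
      box <- bbox(d_low$x[di], d_low$y[di], d_low$w[di], d_low$h[di])
      tracks[[ti]]$state <- kf_update(tracks[[ti]]$state, box)
      tracks[[ti]]$status <- "active"
      tracks[[ti]]$frames_since_update <- 0L
      tracks[[ti]] <- track_record(tracks[[ti]], frame, box, d_low$score[di])
      matched_tracks <- c(matched_tracks, ti)
    }
    remain <- remain[a2$unmatched_tracks]
  }
  # unmatched low-confidence detections are discarded as background

  # unmatched tracks become (or stay) lost; overdue ones are removed
  for (i in remain) {
    tracks[[i]]$status <- "lost"
    tracks[[i]]$frames_since_update <- tracks[[i]]$frames_since_update + 1L
    if (tracks[[i]]$frames_since_update > config$max_lost_frames) {
      tracks[[i]]$status <- "removed"
    }
  }

  # unmatched high-confidence detections start new active tracks
  next_id <- if (length(tracks) == 0) 1L else {
    max(vapply(tracks, `[[`, integer(1), "track_id")) + 1L
  }
  for (di in a1$unmatched_dets) {
    box <- bbox(d_high$x[di], d_high$y[di], d_high$w[di], d_high$h[di])
    tracks[[length(tracks) + 1L]] <- new_track(next_id, box, frame, d_high$score[di])
    next_id <- next_id + 1L
  }

  # cap retained tracks, evicting largest frames_since_update first,
  # breaking ties by smallest track_id
  alive2 <- which(vapply(tracks, function(t) t$status != "removed", logical(1)))
  if (length(alive2) > config$max_tracks) {
    fsu <- vapply(alive2, function(i) tracks[[i]]$frames_since_update, integer(1))
    ids <- vapply(alive2, function(i) tracks[[i]]$track_id, integer(1))
    evict <- alive2[order(-fsu, ids)][seq_len(length(alive2) - config$max_tracks)]
    for (i in evict) tracks[[i]]$status <- "removed"
  }
  tracks
}

#' Track a detection sequence
#'
#' Runs [byte_step()] over consecutive frames and returns every track ever
#' created, with its per-frame box history. Track identities are unique and
#' never reused within a run.
#'
#' @param dets Detections data frame spanning multiple frames.
#' @param config A [tracker_config()].
#' @param frames Optional integer vector of frame indices to process, in
#'   order; defaults to the contiguous range present in `dets`. Frames
#'   without detections are allowed when `frames` is given explicitly;
#'   otherwise a gap in the detection stream is an error.
#' @return List of track objects.
#' @export
track_sequence <- function(dets, config = tracker_config(), frames = NULL) {
  if (nrow(dets) == 0 && is.null(frames)) return(list())
  if (is.null(frames)) {
    present <- sort(unique(dets$frame))
    frames <- seq.int(min(present), max(present))
    if (!identical(as.integer(present), as.integer(frames))) {
      stop("track_sequence: frame indices are not contiguous; pass `frames` explicitly ",
           "if some frames legitimately have no detections")
    }
  }
  tracks <- list()
  for (f in frames) {
    tracks <- byte_step(tracks, dets[dets$frame == f, , drop = FALSE], config, frame = f)
  }
  tracks
}

#' Flatten tracks to a per-frame table
#'
#' @param tracks List of track objects from [track_sequence()].
#' @return Data frame with columns `frame, id, x, y, w, h, conf`, sorted by
#'   `(frame, id)`.
#' @export
tracks_to_table <- function(tracks) {
  if (length(tracks) == 0) {
    return(data.frame(frame = integer(0), id = integer(0), x = numeric(0),
                      y = numeric(0), w = numeric(0), h = numeric(0),
                      conf = numeric(0)))
  }
  out <- do.call(rbind, lapply(tracks, function(t) {
    data.frame(frame = t$frames, id = t$track_id,
               x = t$boxes[, 1], y = t$boxes[, 2],
               w = t$boxes[, 3], h = t$boxes[, 4], conf = t$scores)
  }))
  out <- out[order(out$frame, out$id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
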