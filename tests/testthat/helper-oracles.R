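# Independent oracles: brute-force enumeration counterparts of the
# package's Hungarian-based association and metric matching. These share
# the package's conventions (cost 1 - IoU, lexicographic tie bias, gate
# demotion) but find optima by exhaustive enumeration, so they cannot
# inherit an assignment-algorithm bug.

# all injective maps from 1..k into 1..n as rows of a matrix
injective_maps <- function(k, n) {
  if (k == 0) return(matrix(integer(0), nrow = 1, ncol = 0))
  perms <- function(v, k) {
    if (k == 0) return(list(integer(0)))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i], k - 1)) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  do.call(rbind, perms(seq_len(n), k))
}

# brute-force gated association, mirroring associate()'s conventions
brute_associate <- function(pred_boxes, det_boxes, iou_gate) {
  n <- nrow(pred_boxes)
  m <- nrow(det_boxes)
  empty <- matrix(integer(0), ncol = 2, dimnames = list(NULL, c("track", "det")))
  if (n == 0 || m == 0) {
    return(list(matches = empty, unmatched_tracks = seq_len(n),
                unmatched_dets = seq_len(m)))
  }
  ious <- iou_matrix(pred_boxes, det_boxes)
  eps <- 1e-9 / (n * m + 1)
  bias <- outer(seq_len(n), seq_len(m), function(i, j) (i * (m + 1) + j) * eps)
  cost <- 1 - ious + bias
  best <- NULL
  best_cost <- Inf
  if (n <= m) {
    maps <- injective_maps(n, m)
    for (r in seq_len(nrow(maps))) {
      tc <- sum(cost[cbind(seq_len(n), maps[r, ])])
      if (tc < best_cost) { best_cost <- tc; best <- cbind(seq_len(n), maps[r, ]) }
    }
  } else {
    maps <- injective_maps(m, n)
    for (r in seq_len(nrow(maps))) {
      tc <- sum(cost[cbind(maps[r, ], seq_len(m))])
      if (tc < best_cost) { best_cost <- tc; best <- cbind(maps[r, ], seq_len(m)) }
    }
  }
  ok <- ious[best] >= iou_gate & ious[best] > 0
  matches <- best[ok, , drop = FALSE]
  matches <- matches[order(matches[, 1]), , drop = FALSE]
  colnames(matches) <- c("track", "det")
  list(matches = matches,
       unmatched_tracks = setdiff(seq_len(n), matches[, 1]),
       unmatched_dets = setdiff(seq_len(m), matches[, 2]),
       min_cost = best_cost)
}

# reference CLEAR counts: same carryover convention, remainder matched by
# brute-force enumeration
ref_clear <- function(gt, pred, iou_gate = 0.5) {
  frames <- sort(union(unique(gt$frame), unique(pred$frame)))
  ctp <- 0L; cfp <- 0L; cfn <- 0L; idsw <- 0L
  last_match <- integer(0)
  prev_pairs <- data.frame(gt_id = integer(0), pred_id = integer(0))
  for (f in frames) {
    g <- gt[gt$frame == f, , drop = FALSE]
    p <- pred[pred$frame == f, , drop = FALSE]
    pairs <- data.frame(gt_id = integer(0), pred_id = integer(0))
    for (k in seq_len(nrow(prev_pairs))) {
      gi <- match(prev_pairs$gt_id[k], g$id)
      pi <- match(prev_pairs$pred_id[k], p$id)
      if (!is.na(gi) && !is.na(pi)) {
        o <- iou_matrix(as.matrix(g[gi, c("x", "y", "w", "h")]),
                        as.matrix(p[pi, c("x", "y", "w", "h")]))[1, 1]
        if (o >= iou_gate && o > 0) {
          pairs <- rbind(pairs, data.frame(gt_id = g$id[gi], pred_id = p$id[pi]))
        }
      }
    }
    g2 <- g[!(g$id %in% pairs$gt_id), , drop = FALSE]
    p2 <- p[!(p$id %in% pairs$pred_id), , drop = FALSE]
    res <- brute_associate(as.matrix(g2[, c("x", "y", "w", "h")]),
                           as.matrix(p2[, c("x", "y", "w", "h")]), iou_gate)
    if (nrow(res$matches) > 0) {
      pairs <- rbind(pairs, data.frame(gt_id = g2$id[res$matches[, 1]],
                                       pred_id = p2$id[res$matches[, 2]]))
    }
    ctp <- ctp + nrow(pairs)
    cfn <- cfn + nrow(g) - nrow(pairs)
    cfp <- cfp + nrow(p) - nrow(pairs)
    for (k in seq_len(nrow(pairs))) {
      key <- as.character(pairs$gt_id[k])
      prev <- last_match[key]
      if (!is.na(prev) && prev != pairs$pred_id[k]) idsw <- idsw + 1L
      last_match[key] <- pairs$pred_id[k]
    }
    prev_pairs <- pairs
  }
  list(CTP = ctp, CFP = cfp, CFN = cfn, IDSW = idsw, GT_total = nrow(gt))
}

# reference identity counts: IDTP by exhaustive search over injective
# identity mappings (min total mismatch == max total co-occurrence)
ref_identity <- function(gt, pred, iou_gate = 0.5) {
  gids <- sort(unique(gt$id))
  pids <- sort(unique(pred$id))
  ng <- length(gids)
  np <- length(pids)
  m <- matrix(0L, ng, np)
  for (f in sort(union(unique(gt$frame), unique(pred$frame)))) {
    g <- gt[gt$frame == f, , drop = FALSE]
    p <- pred[pred$frame == f, , drop = FALSE]
    if (nrow(g) == 0 || nrow(p) == 0) next
    ious <- iou_matrix(as.matrix(g[, c("x", "y", "w", "h")]),
                       as.matrix(p[, c("x", "y", "w", "h")]))
    hit <- which(ious >= iou_gate & ious > 0, arr.ind = TRUE)
    for (r in seq_len(nrow(hit))) {
      i <- match(g$id[hit[r, 1]], gids)
      j <- match(p$id[hit[r, 2]], pids)
      m[i, j] <- m[i, j] + 1L
    }
  }
  best <- 0L
  if (ng > 0 && np > 0) {
    k <- min(ng, np)
    # try every injective map of the smaller side, every subset size is
    # dominated by the full-size map since m >= 0
    if (ng <= np) {
      maps <- injective_maps(ng, np)
      for (r in seq_len(nrow(maps))) {
        best <- max(best, sum(m[cbind(seq_len(ng), maps[r, ])]))
      }
    } else {
      maps <- injective_maps(np, ng)
      for (r in seq_len(nrow(maps))) {
        best <- max(best, sum(m[cbind(maps[r, ], seq_len(np))]))
      }
    }
  }
  list(IDTP = as.integer(best),
       IDFP = as.integer(nrow(pred) - best),
       IDFN = as.integer(nrow(gt) - best))
}

ref_mota <- function(cl) 100 * (1 - (cl$CFN + cl$CFP + cl$IDSW) / cl$GT_total)
ref_idf1 <- function(id) 100 * 2 * id$IDTP / (2 * id$IDTP + id$IDFP + id$IDFN)

# random box helper
random_boxes <- function(n, max_xy = 80, max_wh = 30) {
  cbind(x = stats::runif(n, 0, max_xy), y = stats::runif(n, 0, max_xy),
        w = stats::runif(n, 1, max_wh), h = stats::runif(n, 1, max_wh))
}

# random small tracking scenario for metric cross-checks: a ground truth of
# wandering identities plus a degraded prediction (jitter, misses, relabels,
# spurious boxes)
random_mot_scenario <- function(n_ids = 3, n_frames = 12) {
  gt <- list()
  pred <- list()
  starts <- random_boxes(n_ids, max_xy = 60, max_wh = 25)
  starts[, 3:4] <- starts[, 3:4] + 10
  relabel_frame <- sample(n_frames, n_ids, replace = TRUE)
  relabel <- sample(c(TRUE, FALSE), n_ids, replace = TRUE, prob = c(0.3, 0.7))
  for (id in seq_len(n_ids)) {
    pos <- starts[id, 1:2]
    for (f in seq_len(n_frames) - 1L) {
      pos <- pos + stats::rnorm(2, 0, 2)
      if (stats::runif(1) < 0.9) {
        gt[[length(gt) + 1]] <- data.frame(frame = f, id = id, x = pos[1],
                                           y = pos[2], w = starts[id, 3],
                                           h = starts[id, 4])
        if (stats::runif(1) < 0.85) {
          pid <- if (relabel[id] && f >= relabel_frame[id]) id + 100L else id
          pred[[length(pred) + 1]] <- data.frame(
            frame = f, id = pid,
            x = pos[1] + stats::rnorm(1, 0, 1.5),
            y = pos[2] + stats::rnorm(1, 0, 1.5),
            w = starts[id, 3], h = starts[id, 4])
        }
      }
    }
  }
  # a few spurious predictions under their own identities
  for (s in seq_len(sample(0:3, 1))) {
    f <- sample(n_frames, 1) - 1L
    b <- random_boxes(1)
    pred[[length(pred) + 1]] <- data.frame(frame = f, id = 200L + s,
                                           x = b[1], y = b[2],
                                           w = b[3] + 5, h = b[4] + 5)
  }
  empty <- data.frame(frame = integer(0), id = integer(0), x = numeric(0),
                      y = numeric(0), w = numeric(0), h = numeric(0))
  list(gt = if (length(gt)) do.call(rbind, gt) else empty,
       pred = if (length(pred)) do.call(rbind, pred) else empty)
}
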