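# CLEAR and Identity multi-object-tracking evaluation.
#
# Both metric families take ground-truth and predicted per-frame box tables
# (columns frame, id, x, y, w, h) and an IoU gate (default 0.5, the MOT
# convention). CLEAR matching keeps previous-frame correspondences that are
# still within the gate before optimally matching the remainder; Identity
# metrics choose a single global bijection between ground-truth and
# predicted identities minimising total mismatches.

check_annotation_table <- function(df, what) {
  need <- c("frame", "id", "x", "y", "w", "h")
  if (!all(need %in% names(df))) {
    stop(what, ": need columns ", paste(need, collapse = ", "))
  }
  for (f in unique(df$frame)) {
    ids <- df$id[df$frame == f]
    if (anyDuplicated(ids)) stop(what, ": duplicate identity in frame ", f)
  }
  invisible(df)
}

# Gated optimal assignment on 1 - IoU between two box sets; returns k x 2
# index pairs. Shares the tracker's deterministic Hungarian route.
gated_match <- function(A, B, gate) {
  res <- associate(A, B, iou_gate = gate)
  res$matches
}

#' CLEAR correspondence counts
#'
#' Walks the sequence frame by frame. Correspondences from the previous
#' frame are kept while both parties are present and still overlap at least
#' `iou_gate`; the remaining entries are matched by optimal gated
#' assignment. `CTP` counts matched pairs, `CFN` unmatched ground truth,
#' `CFP` unmatched predictions. An identity switch (`IDSW`) is counted when
#' a ground-truth identity's matched predicted identity differs from its
#' most recent previous match; gaps do not reset that memory.
#'
#' @param gt,pred Annotation tables (`frame, id, x, y, w, h`).
#' @param iou_gate Minimum IoU for a valid correspondence.
#' @return List with counts `CTP, CFP, CFN, IDSW`, `GT_total`, and
#'   `correspondences`, a data frame of matched (frame, gt_id, pred_id).
#' @export
clear_match <- function(gt, pred, iou_gate = 0.5) {
  check_annotation_table(gt, "gt")
  check_annotation_table(pred, "pred")
  frames <- sort(union(unique(gt$frame), unique(pred$frame)))
  ctp <- 0L; cfp <- 0L; cfn <- 0L; idsw <- 0L
  last_match <- integer(0) # names: gt id, value: pred id of most recent match
  prev_pairs <- NULL       # data.frame(gt_id, pred_id) matched in previous frame
  corr <- list()
  for (f in frames) {
    g <- gt[gt$frame == f, , drop = FALSE]
    p <- pred[pred$frame == f, , drop = FALSE]
    pairs <- data.frame(gt_id = integer(0), pred_id = integer(0))
    # carry over surviving correspondences
    if (!is.null(prev_pairs) && nrow(prev_pairs) > 0) {
      for (k in seq_len(nrow(prev_pairs))) {
        gi <- match(prev_pairs$gt_id[k], g$id)
        pi <- match(prev_pairs$pred_id[k], p$id)
        if (!is.na(gi) && !is.na(pi)) {
          o <- iou(as_box_matrix(g[gi, ])[1, ], as_box_matrix(p[pi, ])[1, ])
          if (o >= iou_gate && o > 0) {
            pairs <- rbind(pairs, data.frame(gt_id = g$id[gi], pred_id = p$id[pi]))
          }
        }
      }
    }
    g_rest <- g[!(g$id %in% pairs$gt_id), , drop = FALSE]
    p_rest <- p[!(p$id %in% pairs$pred_id), , drop = FALSE]
    m <- gated_match(as_box_matrix(g_rest), as_box_matrix(p_rest), iou_gate)
    if (nrow(m) > 0) {
      pairs <- rbind(pairs, data.frame(gt_id = g_rest$id[m[, 1]],
                                       pred_id = p_rest$id[m[, 2]]))
    }
    ctp <- ctp + nrow(pairs)
    cfn <- cfn + nrow(g) - nrow(pairs)
    cfp <- cfp + nrow(p) - nrow(pairs)
    if (nrow(pairs) > 0) {
      for (k in seq_len(nrow(pairs))) {
        key <- as.character(pairs$gt_id[k])
        prev <- last_match[key]
        if (!is.na(prev) && length(prev) > 0 && prev != pairs$pred_id[k]) {
          idsw <- idsw + 1L
        }
        last_match[key] <- pairs$pred_id[k]
      }
      corr[[length(corr) + 1L]] <- cbind(frame = f, pairs)
    }
    prev_pairs <- pairs
  }
  correspondences <- if (length(corr)) do.call(rbind, corr) else
    data.frame(frame = integer(0), gt_id = integer(0), pred_id = integer(0))
  list(CTP = ctp, CFP = cfp, CFN = cfn, IDSW = idsw,
       GT_total = nrow(gt), correspondences = correspondences)
}

#' MOTA from CLEAR counts
#'
#' `MOTA = 100 * (1 - (CFN + CFP + IDSW) / GT_total)`, in percent. May be
#' negative; never exceeds 100.
#'
#' @param CFN,CFP,IDSW CLEAR counts.
#' @param GT_total Total ground-truth entries (positive).
#' @return Percentage.
#' @export
mota_from_counts <- function(CFN, CFP, IDSW, GT_total) {
  stopifnot(CFN >= 0, CFP >= 0, IDSW >= 0)
  if (GT_total <= 0) stop("mota_from_counts: GT_total must be positive")
  100 * (1 - (CFN + CFP + IDSW) / GT_total)
}

#' Identity metric counts
#'
#' Chooses one global bijective mapping between ground-truth and predicted
#' identities minimising total per-frame mismatches, where a ground-truth
#' entry and a prediction can only cover each other in frames where their
#' IoU reaches the gate. `IDTP` is the number of frame-entries covered by
#' the mapping, `IDFN` the ground-truth entries left uncovered, `IDFP` the
#' predicted entries left uncovered.
#'
#' @param gt,pred Annotation tables.
#' @param iou_gate Minimum IoU for a per-frame co-occurrence.
#' @return List with `IDTP`, `IDFP`, `IDFN` and the chosen `mapping`
#'   (data frame gt_id, pred_id).
#' @export
identity_match <- function(gt, pred, iou_gate = 0.5) {
  check_annotation_table(gt, "gt")
  check_annotation_table(pred, "pred")
  gids <- sort(unique(gt$id))
  pids <- sort(unique(pred$id))
  ng <- length(gids)
  np <- length(pids)
  len_g <- vapply(gids, function(i) sum(gt$id == i), integer(1))
  len_p <- vapply(pids, function(j) sum(pred$id == j), integer(1))
  # co-occurrence counts: frames where gt i and pred j overlap >= gate
  m <- matrix(0L, ng, np)
  if (ng > 0 && np > 0) {
    for (f in sort(union(unique(gt$frame), unique(pred$frame)))) {
      g <- gt[gt$frame == f, , drop = FALSE]
      p <- pred[pred$frame == f, , drop = FALSE]
      if (nrow(g) == 0 || nrow(p) == 0) next
      ious <- iou_matrix(as_box_matrix(g), as_box_matrix(p))
      hit <- which(ious >= iou_gate & ious > 0, arr.ind = TRUE)
      if (nrow(hit) > 0) {
        gi <- match(g$id[hit[, 1]], gids)
        pj <- match(p$id[hit[, 2]], pids)
        for (k in seq_along(gi)) m[gi[k], pj[k]] <- m[gi[k], pj[k]] + 1L
      }
    }
  }
  if (ng == 0 || np == 0) {
    return(list(IDTP = 0L, IDFP = sum(len_p), IDFN = sum(len_g),
                mapping = data.frame(gt_id = integer(0), pred_id = integer(0))))
  }
  # padded square cost: real-real = FN + FP of the pairing; a trajectory may
  # instead fall to its own dummy at the cost of being entirely missed
  big <- sum(len_g) + sum(len_p) + 1
  n <- ng + np
  cost <- matrix(big, n, n)
  cost[seq_len(ng), seq_len(np)] <- outer(len_g, len_p, `+`) - 2 * m
  for (i in seq_len(ng)) cost[i, np + i] <- len_g[i]
  for (j in seq_len(np)) cost[ng + j, j] <- len_p[j]
  cost[(ng + 1):n, (np + 1):n] <- 0
  sol <- as.integer(clue::solve_LSAP(cost))
  idtp <- 0L
  map <- data.frame(gt_id = integer(0), pred_id = integer(0))
  for (i in seq_len(ng)) {
    j <- sol[i]
    if (j <= np) {
      idtp <- idtp + m[i, j]
      map <- rbind(map, data.frame(gt_id = gids[i], pred_id = pids[j]))
    }
  }
  list(IDTP = as.integer(idtp),
       IDFP = as.integer(sum(len_p) - idtp),
       IDFN = as.integer(sum(len_g) - idtp),
       mapping = map)
}

#' IDF1 from identity counts
#'
#' `IDF1 = 100 * 2 IDTP / (2 IDTP + IDFP + IDFN)`, in percent.
#'
#' @param IDTP,IDFP,IDFN Identity counts, non-negative and not all zero.
#' @return Percentage in `[0, 100]`.
#' @export
idf1_from_counts <- function(IDTP, IDFP, IDFN) {
  stopifnot(IDTP >= 0, IDFP >= 0, IDFN >= 0)
  denom <- 2 * IDTP + IDFP + IDFN
  if (denom == 0) stop("idf1_from_counts: all counts are zero")
  100 * 2 * IDTP / denom
}

#' Evaluate tracking output against ground truth
#'
#' Combines [clear_match()] and [identity_match()] into a full report.
#' Inputs may be annotation data frames or paths to MOTChallenge CSV files.
#'
#' @param gt Ground truth: data frame or path.
#' @param pred Predictions: data frame or path.
#' @param iou_gate IoU gate for both metric families.
#' @return A `mot_report` list: CLEAR counts, identity counts, `MOTA` and
#'   `IDF1` percentages.
#' @export
evaluate <- function(gt, pred, iou_gate = 0.5) {
  if (is.character(gt)) gt <- read_mot(gt)
  if (is.character(pred)) pred <- read_mot(pred)
  if (nrow(gt) == 0) stop("evaluate: empty ground truth")
  if (nrow(pred) > 0 &&
      (min(pred$frame) < min(gt$frame) || max(pred$frame) > max(gt$frame))) {
    stop("evaluate: prediction frame range [", min(pred$frame), ", ",
         max(pred$frame), "] falls outside ground-truth range [",
         min(gt$frame), ", ", max(gt$frame), "]")
  }
  cl <- clear_match(gt, pred, iou_gate)
  idm <- identity_match(gt, pred, iou_gate)
  structure(list(
    CTP = cl$CTP, CFP = cl$CFP, CFN = cl$CFN, IDSW = cl$IDSW,
    GT_total = cl$GT_total,
    MOTA = mota_from_counts(cl$CFN, cl$CFP, cl$IDSW, cl$GT_total),
    IDTP = idm$IDTP, IDFP = idm$IDFP, IDFN = idm$IDFN,
    IDF1 = idf1_from_counts(idm$IDTP, idm$IDFP, idm$IDFN),
    iou_gate = iou_gate
  ), class = "mot_report")
}

#' @export
print.mot_report <- function(x, ...) {
  cat("Multi-object tracking evaluation (IoU gate ", x$iou_gate, ")\n", sep = "")
  cat(sprintf("  MOTA %5.1f%%   CTP %d  CFN %d  CFP %d  IDSW %d  (GT %d)\n",
              x$MOTA, x$CTP, x$CFN, x$CFP, x$IDSW, x$GT_total))
  cat(sprintf("  IDF1 %5.1f%%   IDTP %d  IDFN %d  IDFP %d\n",
              x$IDF1, x$IDTP, x$IDFN, x$IDFP))
  invisible(x)
}

#' Write a metric report as a flat key-value file
#'
#' @param report A `mot_report`.
#' @param path Output file; one `key = value` pair per line.
#' @return The path, invisibly.
#' @export
write_report <- function(report, path) {
  keys <- c("MOTA", "IDF1", "CTP", "CFN", "CFP", "IDSW", "GT_total",
            "IDTP", "IDFN", "IDFP", "iou_gate")
  lines <- vapply(keys, function(k) {
    sprintf("%s = %s", k, format(report[[k]], digits = 12))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
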