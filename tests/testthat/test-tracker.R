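make_dets <- function(frame, boxes, scores) {
  detections(rep(frame, length(scores)), boxes[, 1], boxes[, 2],
             boxes[, 3], boxes[, 4], scores)
}

test_that("split_detections separates confidence bands and preserves order", {
  d <- make_dets(0, rbind(c(0, 0, 10, 10), c(20, 0, 10, 10), c(40, 0, 10, 10)),
                 c(0.9, 0.3, 0.05))
  sp <- split_detections(d, tracker_config(tau = 0.5, det_thresh = 0.1))
  expect_equal(sp$high$score, 0.9)
  expect_equal(sp$low$score, 0.3)
  expect_equal(nrow(sp$high) + nrow(sp$low), 2)
  sp0 <- split_detections(d[0, ], tracker_config())
  expect_equal(nrow(sp0$high), 0)
  expect_equal(nrow(sp0$low), 0)
  all_high <- split_detections(make_dets(0, rbind(c(0, 0, 5, 5), c(9, 0, 5, 5)),
                                         c(0.8, 0.7)), tracker_config())
  expect_equal(nrow(all_high$low), 0)
  expect_error(split_detections(detections(c(0, 1), c(0, 0), c(0, 0),
                                           c(5, 5), c(5, 5), c(0.9, 0.9))),
               "single frame")
})

test_that("raising tau only moves detections from high to low", {
  set.seed(21)
  scores <- runif(20)
  d <- make_dets(0, random_boxes(20), scores)
  taus <- sort(runif(5, 0.2, 0.9))
  prev_high <- NULL
  for (tau in taus) {
    sp <- split_detections(d, tracker_config(tau = tau, det_thresh = 0.05))
    if (!is.null(prev_high)) expect_true(all(sp$high$score %in% prev_high))
    prev_high <- sp$high$score
  }
})

test_that("associate matches the gate demotion examples", {
  r <- associate(rbind(c(0, 0, 10, 10)), rbind(c(1, 1, 10, 10)), 0.5)
  expect_equal(nrow(r$matches), 1) # IoU ~ 0.68
  r2 <- associate(rbind(c(0, 0, 10, 10)), rbind(c(50, 50, 10, 10)), 0.5)
  expect_equal(nrow(r2$matches), 0)
  expect_equal(r2$unmatched_tracks, 1)
  expect_equal(r2$unmatched_dets, 1)
  # crosswise IoUs higher: optimal pairing is the crosswise one
  tr <- rbind(c(0, 0, 10, 10), c(20, 0, 10, 10))
  de <- rbind(c(19, 0, 10, 10), c(1, 0, 10, 10))
  r3 <- associate(tr, de, 0.1)
  expect_equal(r3$matches[order(r3$matches[, 1]), 2], c(2, 1))
})

test_that("associate agrees with brute-force optimal assignment", {
  set.seed(31)
  for (case in 1:150) {
    n <- sample(0:5, 1)
    m <- sample(0:5, 1)
    A <- random_boxes(n)
    B <- random_boxes(m)
    gate <- sample(c(0.1, 0.3, 0.5), 1)
    got <- associate(A, B, gate)
    want <- brute_associate(A, B, gate)
    expect_equal(got$matches, want$matches)
    expect_equal(got$unmatched_tracks, want$unmatched_tracks)
    expect_equal(got$unmatched_dets, want$unmatched_dets)
  }
})

test_that("byte_step starts, sustains, and retires tracks per the two-stage rules", {
  cfg <- tracker_config(max_lost_frames = 3)
  # unmatched high-score detection initiates an active track
  tr <- byte_step(list(), make_dets(0, rbind(c(10, 10, 20, 20)), 0.9), cfg)
  expect_length(tr, 1)
  expect_equal(tr[[1]]$status, "active")
  expect_equal(tr[[1]]$track_id, 1L)
  # a low-score overlapping detection is caught by the second stage
  tr2 <- byte_step(tr, make_dets(1, rbind(c(11, 10, 20, 20)), 0.3), cfg)
  expect_length(tr2, 1)
  expect_equal(tr2[[1]]$status, "active")
  expect_equal(tr2[[1]]$frames, c(0L, 1L))
  # a low-score detection never initiates a track
  tr3 <- byte_step(list(), make_dets(0, rbind(c(10, 10, 20, 20)), 0.3), cfg)
  expect_length(tr3, 0)
  # starvation: lost for max_lost_frames, then removed
  trs <- tr
  for (f in 1:3) {
    trs <- byte_step(trs, make_dets(f, rbind(c(0, 0, 1, 1))[0, , drop = FALSE],
                                    numeric(0)), cfg, frame = f)
    expect_equal(trs[[1]]$status, "lost")
  }
  trs <- byte_step(trs, make_dets(4, rbind(c(0, 0, 1, 1))[0, , drop = FALSE],
                                  numeric(0)), cfg, frame = 4)
  expect_equal(trs[[1]]$status, "removed")
  expect_error(byte_step(list(), detections(c(0, 1), c(0, 0), c(0, 0),
                                            c(5, 5), c(5, 5), c(0.9, 0.9))),
               "mixed frames")
})

test_that("alternating high/low scores keep a single identity", {
  frames <- 0:39
  scores <- rep(c(0.9, 0.3), 20)
  d <- detections(frames, rep(50, 40), rep(50, 40), rep(30, 40), rep(20, 40), scores)
  tracks <- track_sequence(d)
  expect_length(tracks, 1)
  expect_equal(tracks[[1]]$frames, frames)
})

test_that("track_sequence recovers separated moving objects exactly", {
  # four parallel lanes at different speeds: boxes never overlap
  o <- lapply(1:4, function(i) {
    object_spec(i, size = c(30, 24), start = c(60, 60 + 70 * (i - 1)),
                velocity = c(0.5 + 0.5 * i, 0))
  })
  sc <- generate_scene(scene_config(n_frames = 100, width = 360, height = 360,
                                    objects = o, master_seed = 4),
                       render = FALSE)
  dets <- perturb_detections(sc, detection_noise(), seed = 4)
  tracks <- track_sequence(dets)
  expect_length(tracks, 4)
  for (t in tracks) expect_equal(t$frames, 0:99)
  # identities are unique, and per-frame box tables consume each detection once
  ids <- vapply(tracks, `[[`, integer(1), "track_id")
  expect_equal(sort(ids), 1:4)
  tab <- tracks_to_table(tracks)
  expect_equal(nrow(tab), nrow(dets))
  expect_false(any(duplicated(tab[, c("frame", "id")])))
})

test_that("tracking is deterministic and never reuses an identity", {
  set.seed(55)
  d <- detections(rep(0:19, each = 3),
                  runif(60, 0, 200), runif(60, 0, 200),
                  runif(60, 15, 40), runif(60, 15, 40), runif(60, 0.05, 1))
  t1 <- track_sequence(d)
  t2 <- track_sequence(d)
  expect_identical(tracks_to_table(t1), tracks_to_table(t2))
  ids <- vapply(t1, `[[`, integer(1), "track_id")
  expect_false(any(duplicated(ids)))
})

test_that("empty detection streams and track caps behave", {
  expect_length(track_sequence(detections(integer(0), numeric(0), numeric(0),
                                          numeric(0), numeric(0), numeric(0))), 0)
  # cap: 6 simultaneous objects with max_tracks 4 retains only 4 non-removed
  d <- detections(rep(0:4, each = 6),
                  rep(seq(0, 250, by = 50), 5), rep(10, 30),
                  rep(20, 30), rep(20, 30), rep(0.9, 30))
  tr <- byte_step(list(), d[d$frame == 0, ], tracker_config(max_tracks = 4))
  alive <- sum(vapply(tr, function(t) t$status != "removed", logical(1)))
  expect_equal(alive, 4)
})
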