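test_that("a static object yields constant boxes and exactly zero flow", {
  o <- object_spec(1, size = c(20, 16), start = c(50, 50))
  sc <- generate_scene(scene_config(n_frames = 10, width = 120, height = 120,
                                    objects = list(o), master_seed = 2))
  expect_equal(nrow(sc$gt), 10)
  expect_equal(length(unique(sc$gt$x)), 1)
  expect_equal(length(unique(sc$gt$w)), 1)
  for (F in sc$flows) {
    expect_true(all(F$du == 0) && all(F$dv == 0))
  }
  # static scene renders identical frames
  expect_identical(sc$frames[[1]], sc$frames[[7]])
})

test_that("constant-velocity motion produces exact displacements and background-zero flow", {
  o <- object_spec(1, size = c(20, 16), start = c(30, 30), velocity = c(3, 4))
  sc <- generate_scene(scene_config(n_frames = 15, width = 160, height = 160,
                                    objects = list(o), master_seed = 3))
  mags <- sqrt(sc$displacement$dx^2 + sc$displacement$dy^2)
  expect_equal(mags, rep(5, 14))
  F <- sc$flows[["0"]]
  moving <- F$du != 0 | F$dv != 0
  expect_true(all(F$du[moving] == 3) && all(F$dv[moving] == 4))
  # ground-truth boxes cover the flow-carrying pixels
  g <- sc$gt[sc$gt$frame == 0, ]
  expect_equal(sum(moving), nrow(pixel_set(bbox(g$x, g$y, g$w, g$h), 160, 160)))
})

test_that("warping frame t by the ground-truth flow reproduces frame t+1", {
  o <- object_spec(1, size = c(30, 22), start = c(60, 60), velocity = c(2, -1))
  sc <- generate_scene(scene_config(n_frames = 6, width = 140, height = 140,
                                    objects = list(o), master_seed = 4))
  for (t in 1:5) {
    f1 <- sc$frames[[t]]
    f2 <- sc$frames[[t + 1]]
    F <- sc$flows[[as.character(t - 1)]]
    h <- nrow(f1); w <- ncol(f1)
    gx <- rep(seq_len(w) - 1, each = h)
    gy <- rep(seq_len(h) - 1, times = w)
    warped <- matrix(pigflow:::interp2(f2, gx + as.vector(F$du), gy + as.vector(F$dv)), h, w)
    moving <- F$du != 0 | F$dv != 0
    expect_lt(max(abs(warped - f1)[moving]), 1e-12)
  }
})

test_that("scene generation is bit-identical under a repeated master seed", {
  cfg <- scene_config(n_frames = 6, width = 100, height = 100, n_objects = 4,
                      master_seed = 11)
  a <- generate_scene(cfg)
  b <- generate_scene(cfg)
  expect_identical(a$frames, b$frames)
  expect_identical(a$gt, b$gt)
  expect_identical(a$flows[["2"]]$du, b$flows[["2"]]$du)
  d1 <- perturb_detections(a, detection_noise(center_jitter_sigma = 2), seed = 5)
  d2 <- perturb_detections(b, detection_noise(center_jitter_sigma = 2), seed = 5)
  expect_identical(d1, d2)
  # generator restores the caller's RNG state
  set.seed(123); before <- runif(3)
  set.seed(123); invisible(generate_scene(cfg)); after <- runif(3)
  expect_identical(before, after)
})

test_that("objects leaving the frame are rejected", {
  o <- object_spec(1, size = c(20, 20),
                   trajectory = cbind(seq(50, 500, length.out = 5), rep(50, 5)))
  expect_error(generate_scene(scene_config(n_frames = 5, width = 100, height = 100,
                                           objects = list(o), master_seed = 1),
                              render = FALSE),
               "leaves the frame")
})

test_that("detection perturbation follows the noise model", {
  o <- lapply(1:3, function(i) object_spec(i, size = c(20, 16),
                                           start = c(30 * i, 30 * i)))
  sc <- generate_scene(scene_config(n_frames = 8, width = 140, height = 140,
                                    objects = o, master_seed = 6),
                       render = FALSE)
  clean <- perturb_detections(sc, detection_noise(), seed = 1)
  expect_equal(nrow(clean), nrow(sc$gt))
  expect_true(all(clean$score == 0.9))
  expect_equal(clean$x + clean$w / 2, sc$gt$x + sc$gt$w / 2)
  none <- perturb_detections(sc, detection_noise(miss_rate = 1), seed = 1)
  expect_equal(nrow(none), 0)
  # centre jitter has the configured spread (Monte-Carlo over 1e4 boxes)
  o1 <- lapply(1:4, function(i) object_spec(i, size = c(20, 16),
                                            start = c(30 * i, 30 * i)))
  sc1 <- generate_scene(scene_config(n_frames = 2500, width = 160, height = 160,
                                     objects = o1, master_seed = 7),
                        render = FALSE)
  jit <- perturb_detections(sc1, detection_noise(center_jitter_sigma = 2), seed = 2)
  gx <- sc1$gt$x + sc1$gt$w / 2
  offs <- c(jit$x + jit$w / 2 - gx, jit$y + jit$h / 2 - (sc1$gt$y + sc1$gt$h / 2))
  expect_lt(abs(sd(offs) - 2) / 2, 0.05)
  # spurious boxes appear at roughly the configured rate, with low scores
  spur <- perturb_detections(sc, detection_noise(spurious_rate = 2), seed = 3)
  extra <- nrow(spur) - nrow(sc$gt)
  expect_gt(extra, 0)
  expect_true(all(spur$score[spur$score != 0.9] <= 0.45))
})

test_that("occlusion drops detection scores of mostly covered objects", {
  # the later-drawn mover crosses the static object, covering > half of it
  o <- list(object_spec(1, size = c(30, 24), start = c(70, 70)),
            object_spec(2, size = c(34, 26), start = c(20, 70), velocity = c(5, 0)))
  sc <- generate_scene(scene_config(n_frames = 22, width = 160, height = 160,
                                    objects = o, master_seed = 9),
                       render = FALSE)
  v1 <- sc$visibility[sc$visibility$id == 1, ]
  expect_lt(min(v1$visible_frac), 0.5)
  expect_equal(max(v1$visible_frac), 1)
  d <- perturb_detections(sc, detection_noise(), seed = 1)
  # amodal boxes: the occluded object's detection keeps its size, low score
  occ_frames <- v1$frame[v1$visible_frac < 0.5]
  low <- d[d$score == 0.3, ]
  expect_setequal(low$frame, occ_frames)
  expect_equal(unique(low$w), 30)
})

test_that("frame decimation keeps every k-th frame", {
  idx <- decimate_frames(2 * 60 * 30, 30, 15)
  expect_length(idx, 1800)
  expect_equal(idx[1:3], c(0L, 2L, 4L))
  expect_length(rep(idx, 4), 7200) # four sub-sequences
  expect_equal(decimate_frames(10, 30, 30), 0:9)
  expect_error(decimate_frames(10, 30, 20), "divide")
})
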