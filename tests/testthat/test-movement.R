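uniform_flow <- function(h, w, dx, dy) flow_field(matrix(dx, h, w), matrix(dy, h, w))

test_that("centre-displacement movement is the Euclidean centre distance", {
  b <- bbox(10, 10, 20, 20)
  expect_equal(bbox_center_movement(b, b), 0)
  expect_equal(bbox_center_movement(bbox(-5, -5, 10, 10), bbox(-2, -1, 10, 10)), 5)
  # Monte-Carlo: i.i.d. Gaussian jitter of consecutive centres gives mean
  # step sigma * sqrt(pi) (the mean norm of a 2D N(0, 2 sigma^2 I) step)
  set.seed(101)
  sigma <- 2
  c0 <- matrix(rnorm(2e4, 0, sigma), ncol = 2)
  c1 <- matrix(rnorm(2e4, 0, sigma), ncol = 2)
  steps <- vapply(seq_len(1e4), function(i) {
    bbox_center_movement(bbox(c0[i, 1] - 5, c0[i, 2] - 5, 10, 10),
                         bbox(c1[i, 1] - 5, c1[i, 2] - 5, 10, 10))
  }, numeric(1))
  expect_true(all(steps > 0))
  expect_lt(abs(mean(steps) - sigma * sqrt(pi)) / (sigma * sqrt(pi)), 0.1)
})

test_that("representative-point movement and propagation follow the field", {
  F <- uniform_flow(32, 32, 3, 4)
  expect_equal(rep_point_movement(F, c(10, 10)), 5)
  expect_equal(rep_point_movement(uniform_flow(32, 32, 0, 0), c(3, 3)), 0)
  expect_equal(rep_point_movement(uniform_flow(32, 32, 1, -1), c(8, 8)), sqrt(2))
  expect_equal(unname(propagate_point(c(10, 10), uniform_flow(32, 32, 1, -2))), c(11, 8))
  expect_equal(unname(propagate_point(c(10, 10), uniform_flow(32, 32, 0, 0))), c(10, 10))
  p <- c(1, 1)
  for (k in 1:5) p <- propagate_point(p, uniform_flow(64, 64, 2, 0))
  expect_equal(unname(p), c(11, 1))
  expect_error(rep_point_movement(F, c(40, 10)), "outside")
})

test_that("mean in-box flow averages magnitudes over the pixel set", {
  F <- uniform_flow(32, 32, 3, 4)
  expect_equal(box_mean_flow_movement(F, bbox(5, 5, 10, 8)), 5)
  expect_equal(box_mean_flow_movement(uniform_flow(32, 32, 0, 0), bbox(5, 5, 10, 8)), 0)
  du <- matrix(0, 32, 32)
  du[11:12, 11] <- 5 # pixels (u=10, v=10) and (u=10, v=11)
  Fp <- flow_field(du, matrix(0, 32, 32))
  expect_equal(box_mean_flow_movement(Fp, bbox(10, 10, 2, 2)), 2.5)
  # clipped box averages over visible pixels only
  expect_equal(box_mean_flow_movement(F, bbox(-10, -10, 20, 20)), 5)
  expect_error(box_mean_flow_movement(F, bbox(100, 100, 5, 5)), "no pixels")
})

test_that("fill-factor law: mean in-box flow is speed times fill fraction", {
  set.seed(7)
  for (case in 1:50) {
    W <- 60L; H <- 60L
    bw <- sample(6:20, 1); bh <- sample(6:20, 1)
    ow <- sample(2:bw, 1); oh <- sample(2:bh, 1)
    bx <- sample(0:(W - bw), 1); by <- sample(0:(H - bh), 1)
    s <- runif(1, 0.5, 6)
    ang <- runif(1, 0, 2 * pi)
    du <- matrix(0, H, W); dv <- matrix(0, H, W)
    # object occupies an ow x oh sub-rectangle of the box
    ox <- bx + sample(0:(bw - ow), 1); oy <- by + sample(0:(bh - oh), 1)
    du[(oy + 1):(oy + oh), (ox + 1):(ox + ow)] <- s * cos(ang)
    dv[(oy + 1):(oy + oh), (ox + 1):(ox + ow)] <- s * sin(ang)
    got <- box_mean_flow_movement(flow_field(du, dv), bbox(bx, by, bw, bh))
    expect_equal(got, s * (ow * oh) / (bw * bh), tolerance = 1e-12)
  }
})

test_that("per-track series assemble records, methods and cumulative sums", {
  # static track, zero ground-truth flow
  tab <- data.frame(frame = 0:9, id = 1L, x = 10, y = 10, w = 8, h = 8)
  flows <- setNames(lapply(0:8, function(t) uniform_flow(40, 40, 0, 0)),
                    as.character(0:8))
  s <- per_track_movement(tab, flows, method = "box_mean_flow")
  expect_equal(nrow(s), 9)
  expect_true(all(s$movement_px == 0))
  expect_true(all(s$cumulative_px == 0))
  # uniform translation: all three estimators agree at speed 5
  n <- 20
  tab2 <- data.frame(frame = 0:(n - 1), id = 2L, x = 5 + 3 * (0:(n - 1)),
                     y = 5 + 4 * (0:(n - 1)), w = 10, h = 10)
  flows2 <- setNames(lapply(seq_len(n - 1) - 1, function(t) uniform_flow(120, 120, 3, 4)),
                     as.character(seq_len(n - 1) - 1))
  for (m in c("bbox_center", "rep_point", "box_mean_flow")) {
    sm <- per_track_movement(tab2, flows2, method = m)
    expect_equal(sm$movement_px, rep(5, n - 1), tolerance = 1e-9)
    expect_equal(sm$cumulative_px[n - 1], 5 * (n - 1), tolerance = 1e-9)
  }
  # track gaps contribute no records
  tab3 <- tab[-5, ] # drop frame 4: pairs (3,4) and (4,5) disappear
  s3 <- per_track_movement(tab3, flows, method = "box_mean_flow")
  expect_equal(nrow(s3), 7)
  expect_false(any(s3$frame %in% c(3L, 4L)))
  expect_error(per_track_movement(tab, flows[1:3], method = "box_mean_flow"),
               "no flow field")
})

test_that("movement values are non-negative with non-decreasing cumulative sums", {
  set.seed(77)
  o <- list(object_spec(1, size = c(24, 18), start = c(40, 40), velocity = c(2, 1)),
            object_spec(2, size = c(20, 20), start = c(100, 100), velocity = c(0, 0)))
  sc <- generate_scene(scene_config(n_frames = 20, width = 160, height = 160,
                                    objects = o, master_seed = 8))
  for (m in c("bbox_center", "rep_point", "box_mean_flow")) {
    s <- per_track_movement(cbind(sc$gt, conf = 1), sc$flows, method = m)
    expect_true(all(s$movement_px >= 0))
    for (id in unique(s$track_id)) {
      expect_true(all(diff(s$cumulative_px[s$track_id == id]) >= -1e-12))
    }
  }
})

test_that("cumulative_movement rebuilds running sums", {
  s <- data.frame(track_id = c(1, 1, 1, 2), frame = c(0, 1, 2, 0),
                  method = "bbox_center", movement_px = c(1, 2, 3, 7),
                  cumulative_px = 0)
  out <- cumulative_movement(s)
  expect_equal(out$cumulative_px, c(1, 3, 6, 7))
  one <- cumulative_movement(s[4, ])
  expect_equal(one$cumulative_px, 7)
})
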