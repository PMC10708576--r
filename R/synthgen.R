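# Synthetic overhead-pen scenes: textured moving and static objects over a
# textured background, with exact ground-truth boxes, identities, per-pixel
# flow, and a configurable detection-noise model (centre/size jitter around
# static objects, misses, spurious boxes, occlusion-driven score drops).
# Everything is a deterministic function of the configured seeds, so every
# pipeline stage can be tested without animal footage.

#' Detection noise model
#'
#' Emulates how a detector misbehaves: box centres and sizes jitter around
#' static objects, occluded objects keep their (amodal) box but drop to a
#' low confidence score, detections go missing, and spurious low-score
#' boxes appear.
#'
#' @param center_jitter_sigma Std. dev. of the Gaussian centre jitter (px).
#' @param size_jitter_sigma Std. dev. of the Gaussian width/height jitter (px).
#' @param miss_rate Per-object per-frame probability of a missed detection.
#' @param spurious_rate Expected spurious boxes per frame (Poisson).
#' @param occlusion_score_drop Score given when visible fraction < 0.5.
#' @param base_score Score of an unoccluded detection.
#' @return A `detection_noise` list.
#' @export
detection_noise <- function(center_jitter_sigma = 0, size_jitter_sigma = 0,
                            miss_rate = 0, spurious_rate = 0,
                            occlusion_score_drop = 0.3, base_score = 0.9) {
  stopifnot(center_jitter_sigma >= 0, size_jitter_sigma >= 0,
            miss_rate >= 0, miss_rate <= 1, spurious_rate >= 0,
            occlusion_score_drop >= 0, occlusion_score_drop <= 1,
            base_score >= 0, base_score <= 1)
  structure(list(center_jitter_sigma = center_jitter_sigma,
                 size_jitter_sigma = size_jitter_sigma,
                 miss_rate = miss_rate, spurious_rate = spurious_rate,
                 occlusion_score_drop = occlusion_score_drop,
                 base_score = base_score),
            class = "detection_noise")
}

#' Synthetic object specification
#'
#' An object is a textured rectangle or ellipse following either an
#' explicit per-frame centre trajectory or a constant-velocity program
#' (reflecting off the frame borders). An optional per-frame size
#' multiplier models the shape change of a stationary animal shifting
#' posture.
#'
#' @param object_id Positive integer identity.
#' @param size `c(w, h)` in pixels.
#' @param shape `"rectangle"` or `"ellipse"`.
#' @param start Initial centre `c(cx, cy)` (used with `velocity`).
#' @param velocity `c(vx, vy)` in pixels/frame.
#' @param trajectory Optional `n_frames x 2` matrix of centres, overriding
#'   `start`/`velocity`.
#' @param texture_seed Integer seed of the object's texture.
#' @param shape_change Optional per-frame size multiplier vector.
#' @return An `object_spec` list.
#' @export
object_spec <- function(object_id, size, shape = c("rectangle", "ellipse"),
                        start = NULL, velocity = c(0, 0), trajectory = NULL,
                        texture_seed = NULL, shape_change = NULL) {
  shape <- match.arg(shape)
  stopifnot(object_id >= 1, length(size) == 2, all(size > 0))
  if (is.null(trajectory) && is.null(start)) {
    stop("object_spec: give either `trajectory` or `start`")
  }
  structure(list(object_id = as.integer(object_id), shape = shape,
                 size = as.numeric(size), start = start,
                 velocity = as.numeric(velocity), trajectory = trajectory,
                 texture_seed = texture_seed, shape_change = shape_change),
            class = "object_spec")
}

#' Synthetic scene configuration
#'
#' Defaults mirror the overhead pig-pen setting the package targets:
#' 640 x 640 frames, 15 fps (metadata only), 4-8 animals per pen. When
#' `objects` is not given, `n_objects` pig-scaled objects are generated
#' from `master_seed`: roughly half move at 1-4 px/frame, the rest are
#' static.
#'
#' @param n_frames Number of frames (>= 2).
#' @param width,height Frame size in pixels.
#' @param fps Frame rate metadata (frames/second).
#' @param n_objects Number of auto-generated objects.
#' @param objects Optional list of [object_spec()]s, drawn in list order
#'   (later objects occlude earlier ones).
#' @param noise A [detection_noise()].
#' @param background_texture_seed Seed of the background texture.
#' @param master_seed Master seed; every random choice derives from it.
#' @return A `scene_config` list.
#' @export
scene_config <- function(n_frames, width = 640, height = 640, fps = 15,
                         n_objects = 6, objects = NULL,
                         noise = detection_noise(),
                         background_texture_seed = NULL, master_seed = 1) {
  stopifnot(n_frames >= 2, width > 0, height > 0, fps > 0, n_objects >= 1)
  structure(list(n_frames = as.integer(n_frames), width = as.integer(width),
                 height = as.integer(height), fps = fps,
                 n_objects = as.integer(n_objects), objects = objects,
                 noise = noise,
                 background_texture_seed = background_texture_seed,
                 master_seed = as.integer(master_seed)),
            class = "scene_config")
}

# band-limited noise texture in [lo, hi]
noise_texture <- function(h, w, seed, sigma = 1.2, lo = 0, hi = 1) {
  with_seed(seed, {
    m <- conv_sep(matrix(stats::runif(h * w), h, w), gaussian_kernel(sigma))
    rng <- range(m)
    lo + (m - rng[1]) / max(rng[2] - rng[1], 1e-12) * (hi - lo)
  })
}

# constant-velocity trajectory with reflection at the centre limits
reflect_trajectory <- function(start, velocity, n, xlim, ylim) {
  traj <- matrix(0, n, 2)
  pos <- as.numeric(start)
  vel <- as.numeric(velocity)
  for (t in seq_len(n)) {
    traj[t, ] <- pos
    pos <- pos + vel
    for (d in 1:2) {
      lim <- if (d == 1) xlim else ylim
      if (pos[d] < lim[1]) { pos[d] <- 2 * lim[1] - pos[d]; vel[d] <- -vel[d] }
      if (pos[d] > lim[2]) { pos[d] <- 2 * lim[2] - pos[d]; vel[d] <- -vel[d] }
    }
  }
  traj
}

auto_objects <- function(config) {
  with_seed(config$master_seed * 7L + 13L, {
    n <- config$n_objects
    specs <- vector("list", n)
    # jittered grid placement keeps initial positions distinct
    grid_n <- ceiling(sqrt(n))
    cells <- sample(grid_n^2, n)
    for (i in seq_len(n)) {
      w0 <- stats::runif(1, 0.12, 0.2) * config$width
      h0 <- stats::runif(1, 0.09, 0.15) * config$height
      gx <- (cells[i] - 1) %% grid_n
      gy <- (cells[i] - 1) %/% grid_n
      cx <- (gx + 0.5) / grid_n * (config$width - w0) + w0 / 2
      cy <- (gy + 0.5) / grid_n * (config$height - h0) + h0 / 2
      moving <- i <= ceiling(n / 2)
      vel <- if (moving) {
        ang <- stats::runif(1, 0, 2 * pi)
        stats::runif(1, 1, 4) * c(cos(ang), sin(ang))
      } else c(0, 0)
      specs[[i]] <- object_spec(
        object_id = i,
        size = c(w0, h0),
        shape = if (i %% 2 == 0) "ellipse" else "rectangle",
        start = c(cx, cy), velocity = vel,
        texture_seed = config$master_seed * 1000L + i)
    }
    specs
  })
}

# 0-based linear indices (column-major) of pixels whose centre lies inside
# the analytic shape; also returns the u/v vectors for flow painting
shape_mask <- function(shape, cx, cy, w, h, width, height) {
  u1 <- max(ceiling(cx - w / 2 - 0.5), 0)
  u2 <- min(ceiling(cx + w / 2 - 0.5) - 1, width - 1)
  v1 <- max(ceiling(cy - h / 2 - 0.5), 0)
  v2 <- min(ceiling(cy + h / 2 - 0.5) - 1, height - 1)
  if (u2 < u1 || v2 < v1) return(cbind(u = integer(0), v = integer(0)))
  us <- seq.int(u1, u2)
  vs <- seq.int(v1, v2)
  uu <- rep(us, each = length(vs))
  vv <- rep(vs, times = length(us))
  if (shape == "ellipse") {
    keep <- ((uu + 0.5 - cx) / (w / 2))^2 + ((vv + 0.5 - cy) / (h / 2))^2 <= 1
    uu <- uu[keep]
    vv <- vv[keep]
  }
  cbind(u = uu, v = vv)
}

#' Generate a synthetic overhead scene
#'
#' Renders textured objects over a textured background along their
#' trajectories (later-listed objects occlude earlier ones, painter's
#' algorithm) and returns the frames together with full ground truth:
#' per-frame identity boxes (amodal — occlusion does not shrink them),
#' exact per-pixel flow for every frame pair (object pixels carry the
#' object's centre displacement, background is exactly zero, occluded
#' pixels carry the occluder's displacement), per-object centre
#' displacements, and per-object visible fractions. Sub-pixel positions
#' are rendered by bilinear texture sampling, so constant-velocity motion
#' is smooth rather than integer-snapped.
#'
#' @param config A [scene_config()].
#' @param render Render frames and ground-truth flow fields. With
#'   `render = FALSE` only boxes, displacements and visibility are
#'   produced, which is much lighter for tracker-only studies.
#' @return A `synthetic_scene` list: `frames` (list of H x W matrices in
#'   `[0,1]`, or `NULL`), `gt` (frame, id, x, y, w, h), `flows` (named list
#'   of [flow_field()]s, element `"t"` for pair `t -> t+1`, or `NULL`),
#'   `displacement` (frame, id, dx, dy), `visibility` (frame, id,
#'   visible_frac), and `config`.
#' @export
generate_scene <- function(config, render = TRUE) {
  objects <- config$objects
  if (is.null(objects)) objects <- auto_objects(config)
  n <- config$n_frames
  W <- config$width
  H <- config$height

  # resolve trajectories and per-frame sizes
  trajs <- list()
  sizes <- list()
  for (i in seq_along(objects)) {
    o <- objects[[i]]
    tr <- if (!is.null(o$trajectory)) {
      stopifnot(nrow(o$trajectory) == n)
      o$trajectory
    } else {
      reflect_trajectory(o$start, o$velocity, n,
                         c(o$size[1] / 2, W - o$size[1] / 2),
                         c(o$size[2] / 2, H - o$size[2] / 2))
    }
    mult <- if (is.null(o$shape_change)) rep(1, n) else {
      stopifnot(length(o$shape_change) == n)
      o$shape_change
    }
    sz <- cbind(w = o$size[1] * mult, h = o$size[2] * mult)
    # every object must stay at least partially inside the frame
    for (t in seq_len(n)) {
      bx <- bbox(tr[t, 1] - sz[t, 1] / 2, tr[t, 2] - sz[t, 2] / 2, sz[t, 1], sz[t, 2])
      cl <- clip_bbox(bx, W, H)
      if (cl[[3]] <= 0 || cl[[4]] <= 0) {
        stop("generate_scene: object ", o$object_id, " leaves the frame at frame ", t - 1)
      }
    }
    trajs[[i]] <- tr
    sizes[[i]] <- sz
  }

  bg_seed <- config$background_texture_seed
  if (is.null(bg_seed)) bg_seed <- config$master_seed * 31L + 7L
  textures <- lapply(seq_along(objects), function(i) {
    o <- objects[[i]]
    ts <- if (is.null(o$texture_seed)) config$master_seed * 1000L + i else o$texture_seed
    # alternate dark/bright texture bands so objects contrast with the background
    if (i %% 2 == 0) {
      noise_texture(max(ceiling(o$size[2]), 4), max(ceiling(o$size[1]), 4), ts,
                    lo = 0.62, hi = 1)
    } else {
      noise_texture(max(ceiling(o$size[2]), 4), max(ceiling(o$size[1]), 4), ts,
                    lo = 0, hi = 0.38)
    }
  })
  bg <- if (render) noise_texture(H, W, bg_seed, lo = 0.42, hi = 0.58) else NULL

  k <- length(objects)
  ids <- vapply(objects, `[[`, integer(1), "object_id")
  gt_frame <- rep(seq_len(n) - 1L, each = k)
  gt_id <- rep(ids, times = n)
  gt_x <- gt_y <- gt_w <- gt_h <- numeric(n * k)
  vis_frac <- numeric(n * k)
  frames <- if (render) vector("list", n) else NULL
  flows <- if (render) stats::setNames(vector("list", n - 1),
                                       as.character(seq_len(n - 1) - 1L)) else NULL

  masks_prev <- NULL
  for (t in seq_len(n)) {
    img <- if (render) bg else NULL
    owner <- matrix(0L, H, W)
    masks <- vector("list", k)
    for (i in seq_len(k)) {
      o <- objects[[i]]
      cx <- trajs[[i]][t, 1]; cy <- trajs[[i]][t, 2]
      w <- sizes[[i]][t, 1]; h <- sizes[[i]][t, 2]
      mk <- shape_mask(o$shape, cx, cy, w, h, W, H)
      masks[[i]] <- mk
      if (nrow(mk) > 0) {
        lin <- mk[, "v"] + 1L + mk[, "u"] * H
        owner[lin] <- i
        if (render) {
          Tm <- textures[[i]]
          tx <- ((mk[, "u"] + 0.5 - cx) / w + 0.5) * (ncol(Tm) - 1)
          ty <- ((mk[, "v"] + 0.5 - cy) / h + 0.5) * (nrow(Tm) - 1)
          img[lin] <- interp2(Tm, tx, ty)
        }
      }
      r <- (t - 1L) * k + i
      gt_x[r] <- cx - w / 2; gt_y[r] <- cy - h / 2
      gt_w[r] <- w; gt_h[r] <- h
    }
    for (i in seq_len(k)) {
      mk <- masks[[i]]
      vis_frac[(t - 1L) * k + i] <- if (nrow(mk) == 0) 0 else {
        lin <- mk[, "v"] + 1L + mk[, "u"] * H
        sum(owner[lin] == i) / nrow(mk)
      }
    }
    if (render) {
      frames[[t]] <- img
      if (t > 1) {
        du <- matrix(0, H, W)
        dv <- matrix(0, H, W)
        for (i in seq_len(k)) {
          mk <- masks_prev[[i]]
          if (nrow(mk) > 0) {
            lin <- mk[, "v"] + 1L + mk[, "u"] * H
            d <- trajs[[i]][t, ] - trajs[[i]][t - 1, ]
            du[lin] <- d[1]
            dv[lin] <- d[2]
          }
        }
        flows[[as.character(t - 2L)]] <- flow_field(du, dv)
      }
    }
    masks_prev <- masks
  }

  disp <- data.frame(
    frame = rep(seq_len(n - 1) - 1L, each = k),
    id = rep(ids, times = n - 1),
    dx = as.vector(vapply(seq_len(n - 1), function(t)
      vapply(seq_len(k), function(i) trajs[[i]][t + 1, 1] - trajs[[i]][t, 1],
             numeric(1)), numeric(k))),
    dy = as.vector(vapply(seq_len(n - 1), function(t)
      vapply(seq_len(k), function(i) trajs[[i]][t + 1, 2] - trajs[[i]][t, 2],
             numeric(1)), numeric(k))))
  structure(list(frames = frames,
                 gt = data.frame(frame = gt_frame, id = gt_id, x = gt_x,
                                 y = gt_y, w = gt_w, h = gt_h),
                 flows = flows,
                 displacement = disp,
                 visibility = data.frame(frame = gt_frame, id = gt_id,
                                         visible_frac = vis_frac),
                 config = config),
            class = "synthetic_scene")
}

#' Perturb ground-truth boxes into noisy detections
#'
#' Applies the detection-noise model to a scene's ground truth: each box is
#' dropped with `miss_rate`, otherwise its centre and size receive
#' independent zero-mean Gaussian perturbations; the score is `base_score`,
#' or `occlusion_score_drop` when the object's visible fraction is below
#' one half; spurious low-score boxes are added as a per-frame Poisson
#' process. Deterministic given `seed`.
#'
#' @param scene A `synthetic_scene` (or any list with `gt`, `visibility`
#'   and `config` of the same shape).
#' @param noise A [detection_noise()]; defaults to the scene's.
#' @param seed RNG seed.
#' @return A detections data frame (`frame, x, y, w, h, score`).
#' @export
perturb_detections <- function(scene, noise = NULL, seed = 1) {
  if (is.null(noise)) noise <- scene$config$noise
  gt <- scene$gt
  vis <- scene$visibility
  W <- scene$config$width
  H <- scene$config$height
  with_seed(seed, {
    ng <- nrow(gt)
    keep <- stats::runif(ng) >= noise$miss_rate
    cx <- gt$x + gt$w / 2 + stats::rnorm(ng, 0, noise$center_jitter_sigma)
    cy <- gt$y + gt$h / 2 + stats::rnorm(ng, 0, noise$center_jitter_sigma)
    w <- pmax(gt$w + stats::rnorm(ng, 0, noise$size_jitter_sigma), 2)
    h <- pmax(gt$h + stats::rnorm(ng, 0, noise$size_jitter_sigma), 2)
    frac <- vis$visible_frac[match(paste(gt$frame, gt$id),
                                   paste(vis$frame, vis$id))]
    score <- ifelse(!is.na(frac) & frac < 0.5, noise$occlusion_score_drop,
                    noise$base_score)
    true_dets <- data.frame(frame = gt$frame, x = cx - w / 2, y = cy - h / 2,
                            w = w, h = h, score = score)[keep, , drop = FALSE]
    frames_all <- sort(unique(gt$frame))
    n_spur <- if (noise$spurious_rate > 0) {
      stats::rpois(length(frames_all), noise$spurious_rate)
    } else rep(0L, length(frames_all))
    ns <- sum(n_spur)
    spur <- if (ns > 0) {
      sw <- stats::runif(ns, 20, 80)
      sh <- stats::runif(ns, 20, 80)
      data.frame(frame = rep(frames_all, n_spur),
                 x = stats::runif(ns, 0, pmax(W - sw, 1)),
                 y = stats::runif(ns, 0, pmax(H - sh, 1)),
                 w = sw, h = sh, score = stats::runif(ns, 0.1, 0.45))
    } else NULL
    res <- rbind(true_dets, spur)
    res <- res[order(res$frame), , drop = FALSE]
    rownames(res) <- NULL
    res
  })
}

#' Frame-rate decimation indices
#'
#' Indices (0-based) of the frames retained when reducing a sequence from
#' `src_fps` to `dst_fps`: every `(src_fps/dst_fps)`-th frame starting at 0.
#'
#' @param n_source_frames Number of frames at the source rate.
#' @param src_fps,dst_fps Source and target frame rates; `dst_fps` must
#'   divide `src_fps`.
#' @return Integer vector of retained 0-based frame indices.
#' @examples
#' length(decimate_frames(2 * 60 * 30, 30, 15)) # 1800
#' @export
decimate_frames <- function(n_source_frames, src_fps, dst_fps) {
  stopifnot(n_source_frames >= 1, src_fps > 0, dst_fps > 0)
  step <- src_fps / dst_fps
  if (step != round(step)) {
    stop("decimate_frames: dst_fps (", dst_fps, ") must divide src_fps (", src_fps, ")")
  }
  seq.int(0L, n_source_frames - 1L, by = as.integer(step))
}

#' Write a scene to disk
#'
#' Frames go out as zero-padded grayscale PNGs (`frame_000000.png`, ...),
#' ground truth as MOTChallenge `gt.txt`, ground-truth flow as Middlebury
#' `flow_<t>.flo` per frame pair, and the full configuration as a
#' `manifest.txt` key-value file.
#'
#' @param scene A rendered `synthetic_scene`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(scene$frames)) {
    for (t in seq_along(scene$frames)) {
      png::writePNG(scene$frames[[t]],
                    file.path(dir, sprintf("frame_%06d.png", t - 1L)))
    }
  }
  gt <- scene$gt
  gt$conf <- 1
  write_mot(gt, file.path(dir, "gt.txt"))
  if (!is.null(scene$flows)) {
    for (nm in names(scene$flows)) {
      write_flo(scene$flows[[nm]],
                file.path(dir, sprintf("flow_%06d.flo", as.integer(nm))))
    }
  }
  cfg <- scene$config
  manifest <- list(width = cfg$width, height = cfg$height,
                   n_frames = cfg$n_frames, fps = cfg$fps,
                   n_objects = length(unique(scene$gt$id)),
                   master_seed = cfg$master_seed,
                   center_jitter_sigma = cfg$noise$center_jitter_sigma,
                   size_jitter_sigma = cfg$noise$size_jitter_sigma,
                   miss_rate = cfg$noise$miss_rate,
                   spurious_rate = cfg$noise$spurious_rate,
                   occlusion_score_drop = cfg$noise$occlusion_score_drop,
                   base_score = cfg$noise$base_score)
  write_manifest(manifest, file.path(dir, "manifest.txt"))
  invisible(dir)
}
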