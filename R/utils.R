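# Internal numerical helpers shared by the flow estimator and the scene
# generator. Images are plain numeric matrices, rows = y (top to bottom),
# cols = x; pixel (u, v) in 0-based image coordinates lives at [v + 1, u + 1].

# Bilinear interpolation at 0-based coordinates (x, y), replicate padding
# outside the grid. x and y are vectors of equal length.
interp2 <- function(img, x, y) {
  h <- nrow(img)
  w <- ncol(img)
  x <- pmin(pmax(x, 0), w - 1)
  y <- pmin(pmax(y, 0), h - 1)
  x0 <- pmin(floor(x), max(w - 2, 0))
  y0 <- pmin(floor(y), max(h - 2, 0))
  fx <- x - x0
  fy <- y - y0
  x1 <- pmin(x0 + 1, w - 1)
  y1 <- pmin(y0 + 1, h - 1)
  i00 <- img[cbind(y0 + 1, x0 + 1)]
  i10 <- img[cbind(y0 + 1, x1 + 1)]
  i01 <- img[cbind(y1 + 1, x0 + 1)]
  i11 <- img[cbind(y1 + 1, x1 + 1)]
  (1 - fy) * ((1 - fx) * i00 + fx * i10) + fy * ((1 - fx) * i01 + fx * i11)
}

# Resize a matrix to new dimensions by bilinear sampling (align-corners).
resize_bilinear <- function(img, new_h, new_w) {
  h <- nrow(img)
  w <- ncol(img)
  xs <- if (new_w == 1) 0 else seq(0, w - 1, length.out = new_w)
  ys <- if (new_h == 1) 0 else seq(0, h - 1, length.out = new_h)
  grid_x <- rep(xs, each = new_h)
  grid_y <- rep(ys, times = new_w)
  matrix(interp2(img, grid_x, grid_y), nrow = new_h, ncol = new_w)
}

gaussian_kernel <- function(sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# Separable convolution with replicate padding, kernel applied along both axes.
conv_sep <- function(img, k) {
  r <- (length(k) - 1L) %/% 2L
  h <- nrow(img)
  w <- ncol(img)
  # horizontal pass
  pad <- img[, c(rep(1L, r), seq_len(w), rep(w, r)), drop = FALSE]
  out <- matrix(0, h, w)
  for (i in seq_along(k)) out <- out + k[i] * pad[, i:(i + w - 1L), drop = FALSE]
  # vertical pass
  pad <- out[c(rep(1L, r), seq_len(h), rep(h, r)), , drop = FALSE]
  res <- matrix(0, h, w)
  for (i in seq_along(k)) res <- res + k[i] * pad[i:(i + h - 1L), , drop = FALSE]
  res
}

# Run code with a given RNG seed, restoring the caller's RNG state afterwards
# so generator determinism never leaks into user sessions.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# 3x3 median filter via a fixed comparator network on nine shifted copies
# (replicate padding). Used to clean flow fields at motion boundaries.
median3x3 <- function(m) {
  h <- nrow(m)
  w <- ncol(m)
  if (h < 2 || w < 2) return(m)
  up <- c(1L, seq_len(h - 1L))
  dn <- c(seq_len(h - 1L) + 1L, h)
  lf <- c(1L, seq_len(w - 1L))
  rt <- c(seq_len(w - 1L) + 1L, w)
  p <- list(
    m[up, lf], m[up, ], m[up, rt],
    m[, lf],   m,       m[, rt],
    m[dn, lf], m[dn, ], m[dn, rt]
  )
  swp <- function(i, j) {
    lo <- pmin(p[[i]], p[[j]])
    hi <- pmax(p[[i]], p[[j]])
    p[[i]] <<- lo
    p[[j]] <<- hi
  }
  # 19-exchange median-of-9 network (Paeth)
  swp(2, 3); swp(5, 6); swp(8, 9)
  swp(1, 2); swp(4, 5); swp(7, 8)
  swp(2, 3); swp(5, 6); swp(8, 9)
  swp(1, 4); swp(6, 9); swp(5, 8)
  swp(4, 7); swp(2, 5); swp(3, 6)
  swp(5, 8); swp(5, 3); swp(7, 5)
  swp(5, 3)
  p[[5]]
}
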