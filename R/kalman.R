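# SORT-style constant-velocity Kalman filter over box state
# (cx, cy, a, h, vcx, vcy, va, vh), where a = w/h is the aspect ratio.
# Process and measurement noise standard deviations scale with box height
# (weights 1/20 for positions, 1/160 for velocities), the convention used
# throughout the SORT/BYTE family of trackers.

.kf_std_pos <- 1 / 20
.kf_std_vel <- 1 / 160

.kf_F <- local({
  f <- diag(8)
  f[1:4, 5:8] <- diag(4)
  f
})
.kf_H <- cbind(diag(4), matrix(0, 4, 4))

box_to_z <- function(box) {
  c(box[[1]] + box[[3]] / 2, box[[2]] + box[[4]] / 2, box[[3]] / box[[4]], box[[4]])
}

z_to_box <- function(z) {
  w <- z[3] * z[4]
  bbox(z[1] - w / 2, z[2] - z[4] / 2, max(w, 0), max(z[4], 0))
}

#' Initialise a Kalman track state from a detection box
#'
#' The state mean holds the box centre, aspect ratio and height with zero
#' velocities; the initial covariance scales with box height.
#'
#' @param box A box with positive area.
#' @return A `kalman_state`: list with `mean` (length-8) and `cov` (8 x 8).
#' @export
kf_initiate <- function(box) {
  if (box[[3]] <= 0 || box[[4]] <= 0) stop("kf_initiate: box must have positive area")
  z <- box_to_z(box)
  h <- z[4]
  std <- c(2 * .kf_std_pos * h, 2 * .kf_std_pos * h, 1e-2, 2 * .kf_std_pos * h,
           10 * .kf_std_vel * h, 10 * .kf_std_vel * h, 1e-5, 10 * .kf_std_vel * h)
  structure(list(mean = c(z, rep(0, 4)), cov = diag(std^2)), class = "kalman_state")
}

#' Predict the next-frame state
#'
#' Constant-velocity propagation: positions advance by velocities, the
#' covariance grows by height-scaled process noise.
#'
#' @param state A `kalman_state`.
#' @return The propagated `kalman_state`.
#' @seealso [kf_box()] for the predicted box.
#' @export
kf_predict <- function(state) {
  h <- state$mean[4]
  std <- c(.kf_std_pos * h, .kf_std_pos * h, 1e-2, .kf_std_pos * h,
           .kf_std_vel * h, .kf_std_vel * h, 1e-5, .kf_std_vel * h)
  mean <- as.numeric(.kf_F %*% state$mean)
  cov <- .kf_F %*% state$cov %*% t(.kf_F) + diag(std^2)
  structure(list(mean = mean, cov = (cov + t(cov)) / 2), class = "kalman_state")
}

#' Correct a state with a measured box
#'
#' Standard linear-Gaussian update of `(cx, cy, a, h)` toward the
#' measurement; the posterior variance in the measured subspace never
#' exceeds the prior's.
#'
#' @param state A `kalman_state`.
#' @param box The measured box (positive area).
#' @return The updated `kalman_state`.
#' @export
kf_update <- function(state, box) {
  if (box[[3]] <= 0 || box[[4]] <= 0) stop("kf_update: measurement box must have positive area")
  z <- box_to_z(box)
  h <- state$mean[4]
  std <- c(.kf_std_pos * h, .kf_std_pos * h, 1e-1, .kf_std_pos * h)
  S <- .kf_H %*% state$cov %*% t(.kf_H) + diag(std^2)
  K <- state$cov %*% t(.kf_H) %*% solve(S)
  innov <- z - as.numeric(.kf_H %*% state$mean)
  mean <- state$mean + as.numeric(K %*% innov)
  cov <- (diag(8) - K %*% .kf_H) %*% state$cov
  structure(list(mean = mean, cov = (cov + t(cov)) / 2), class = "kalman_state")
}

#' Box implied by a Kalman state mean
#'
#' @param state A `kalman_state`.
#' @return A box `c(x, y, w, h)`.
#' @export
kf_box <- function(state) {
  z_to_box(state$mean[1:4])
}
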