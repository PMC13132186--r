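# Constant-velocity Kalman filter on the measurement (cx, cy, a, h):
# box center, aspect ratio w/h and height, plus their per-frame velocities,
# giving the 8-dimensional state used throughout multi-object tracking.
# Uncertainties scale with box height so large (near) animals tolerate
# proportionally larger innovations than distant ones.

KF_DIM <- 8L

# Noise weights. Position/size noise is a fraction of box height per frame;
# the velocity weights keep the filter responsive enough that a constant
# velocity target is locked onto within a handful of frames.
KF_STD_POS <- 1 / 20
KF_STD_VEL <- 1 / 10

kf_transition <- function() {
  f <- diag(KF_DIM)
  f[cbind(1:4, 5:8)] <- 1
  f
}

kf_measurement_matrix <- function() {
  h <- matrix(0, 4, KF_DIM)
  h[cbind(1:4, 1:4)] <- 1
  h
}

det_to_measurement <- function(d) {
  b <- unname(d$box)
  c(b[1] + b[3] / 2, b[2] + b[4] / 2, b[3] / b[4], b[4])
}

#' Initialize a Kalman state from a detection
#'
#' State is `(cx, cy, a, h, vcx, vcy, va, vh)` with zero initial velocities;
#' the initial covariance scales with the detection height.
#'
#' @param d a detection (see [detection()]).
#' @return List with `mean` (length 8) and `covariance` (8 x 8).
#' @export
kf_init <- function(d) {
  if (d$box[4] <= 0) stop("cannot initialize a Kalman state from a zero-height detection")
  z <- det_to_measurement(d)
  mean <- c(z, rep(0, 4))
  h <- z[4]
  std <- c(2 * KF_STD_POS * h, 2 * KF_STD_POS * h, 1e-2, 2 * KF_STD_POS * h,
           10 * KF_STD_VEL * h, 10 * KF_STD_VEL * h, 1e-5, 10 * KF_STD_VEL * h)
  list(mean = mean, covariance = diag(std^2))
}

#' Kalman prediction step
#'
#' Constant-velocity propagation: positions advance by one frame's velocity
#' and the covariance grows by height-scaled process noise.
#'
#' @param s Kalman state from [kf_init()] / [kf_update()].
#' @return Predicted state.
#' @export
kf_predict <- function(s) {
  f <- kf_transition()
  h <- max(s$mean[4], 1e-6)
  std <- c(KF_STD_POS * h, KF_STD_POS * h, 1e-2, KF_STD_POS * h,
           KF_STD_VEL * h, KF_STD_VEL * h, 1e-5, KF_STD_VEL * h)
  q <- diag(std^2)
  list(mean = as.numeric(f %*% s$mean),
       covariance = f %*% s$covariance %*% t(f) + q)
}

#' Kalman measurement update
#'
#' Standard linear update against the detection's `(cx, cy, a, h)`
#' measurement; the posterior covariance is symmetrized and, if numerical
#' error drives an eigenvalue negative, clamped to PSD.
#'
#' @param s predicted Kalman state.
#' @param d matched detection.
#' @return Posterior state.
#' @export
kf_update <- function(s, d) {
  z <- det_to_measurement(d)
  hm <- kf_measurement_matrix()
  hgt <- max(s$mean[4], 1e-6)
  rstd <- c(KF_STD_POS * hgt, KF_STD_POS * hgt, 1e-1, KF_STD_POS * hgt)
  r <- diag(rstd^2)
  ss <- hm %*% s$covariance %*% t(hm) + r
  k <- s$covariance %*% t(hm) %*% solve(ss)
  innov <- z - as.numeric(hm %*% s$mean)
  mean <- as.numeric(s$mean + k %*% innov)
  cov <- (diag(KF_DIM) - k %*% hm) %*% s$covariance
  cov <- (cov + t(cov)) / 2
  ev <- eigen(cov, symmetric = TRUE)
  if (any(ev$values < -1e-6)) stop("Kalman update produced a non-PSD covariance")
  if (any(ev$values < 0)) {
    vals <- pmax(ev$values, 0)
    cov <- ev$vectors %*% diag(vals) %*% t(ev$vectors)
  }
  list(mean = mean, covariance = cov)
}

# Current box implied by the filter state. The linear filter does not
# constrain aspect or height to stay positive, so clamp defensively.
kf_box <- function(s) {
  h <- max(s$mean[4], 1e-3)
  w <- max(s$mean[3], 1e-3) * h
  box_from_center(s$mean[1], s$mean[2], w, h)
}
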