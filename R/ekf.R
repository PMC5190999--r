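## Extended Kalman filter estimating the elbow flexion-extension angle, rate
## and acceleration from a forearm-mounted IMU (one sagittal-plane DOF).
##
## State x = (theta, theta_dot, theta_ddot). theta is the angle between the
## sensor Y axis and gravity: 0 with the forearm hanging vertically, positive
## in flexion. The process model is the continuous Wiener-process-acceleration
## (CWPA) kinematic model; the measurement model maps the state to the X/Y
## accelerometer channels (gravity plus tangential / centripetal terms at
## lever arm l) and the X gyroscope channel.

#' EKF configuration
#'
#' @param l elbow-to-sensor distance along the forearm (m).
#' @param g gravity magnitude (m/s^2).
#' @param tau sampling period (s); 0.02 s for the 50 Hz working rate.
#' @param q CWPA process-noise intensity, the white-jerk spectral density
#'   ((rad/s^3)^2 s). Larger values let the filter track faster angular
#'   acceleration changes at the cost of noisier estimates.
#' @param accel_sd,gyro_sd measurement noise standard deviations used to
#'   build the default diagonal measurement covariance `R` (m/s^2, rad/s).
#' @param R optional full 3x3 measurement-noise covariance overriding the
#'   diagonal default.
#' @param P0 initial state covariance (3x3).
#' @return object of class `ekf_config`.
#' @export
ekf_config <- function(l = 0.15, g = 9.81, tau = 0.02, q = 10,
                       accel_sd = 0.2, gyro_sd = 0.02,
                       R = NULL, P0 = diag(c(0.1, 0.1, 1))) {
  if (l <= 0 || g <= 0 || tau <= 0) stopf("l, g and tau must be positive")
  if (q < 0) stopf("process-noise intensity q must be nonnegative")
  if (is.null(R)) R <- diag(c(accel_sd^2, accel_sd^2, gyro_sd^2))
  R <- as.matrix(R)
  if (!isTRUE(all.equal(R, t(R))) || any(eigen(R, symmetric = TRUE, only.values = TRUE)$values <= 0)) {
    stopf("R must be symmetric positive definite")
  }
  structure(list(l = l, g = g, tau = tau, q = q, R = R, P0 = as.matrix(P0)),
            class = "ekf_config")
}

#' @export
print.ekf_config <- function(x, ...) {
  cat(sprintf("EKF config: l = %.3f m, g = %.2f m/s^2, tau = %.4f s, q = %g\n",
              x$l, x$g, x$tau, x$q))
  invisible(x)
}

#' CWPA state-transition matrix
#'
#' @param tau sampling period (s).
#' @return 3x3 matrix `A` with rows (1, tau, tau^2/2), (0, 1, tau), (0, 0, 1).
#' @export
ekf_process_matrix <- function(tau) {
  if (tau <= 0) stopf("tau must be positive")
  matrix(c(1, tau, tau^2 / 2,
           0, 1, tau,
           0, 0, 1), nrow = 3, byrow = TRUE)
}

#' Discretized CWPA process-noise covariance
#'
#' Standard discretization of white jerk with intensity `q` over one sample
#' period.
#'
#' @param tau sampling period (s).
#' @param q white-jerk intensity ((rad/s^3)^2 s).
#' @return symmetric 3x3 covariance matrix.
#' @export
ekf_process_noise <- function(tau, q) {
  if (tau <= 0) stopf("tau must be positive")
  if (q < 0) stopf("q must be nonnegative")
  q * matrix(c(tau^5 / 20, tau^4 / 8, tau^3 / 6,
               tau^4 / 8,  tau^3 / 3, tau^2 / 2,
               tau^3 / 6,  tau^2 / 2, tau), nrow = 3, byrow = TRUE)
}

#' Noise-free measurement prediction
#'
#' Maps a state to the expected IMU reading: X accelerometer
#' `-g sin(theta) + theta_ddot * l` (gravity plus tangential acceleration),
#' Y accelerometer `-g cos(theta) + theta_dot^2 * l` (gravity plus
#' centripetal acceleration), X gyroscope `theta_dot`.
#'
#' @param x state vector `c(theta, theta_dot, theta_ddot)`.
#' @param cfg an [ekf_config()].
#' @return numeric vector `c(ax, ay, wx)`.
#' @export
ekf_measure <- function(x, cfg) {
  c(-cfg$g * sin(x[1]) + x[3] * cfg$l,
    -cfg$g * cos(x[1]) + x[2]^2 * cfg$l,
    x[2])
}

#' Measurement Jacobian
#'
#' Partial derivatives of [ekf_measure()] with respect to the state,
#' evaluated at `x`.
#'
#' @inheritParams ekf_measure
#' @return 3x3 matrix.
#' @export
ekf_measurement_jacobian <- function(x, cfg) {
  matrix(c(-cfg$g * cos(x[1]), 0,                 cfg$l,
           cfg$g * sin(x[1]),  2 * x[2] * cfg$l,  0,
           0,                  1,                 0), nrow = 3, byrow = TRUE)
}

#' EKF state container
#'
#' @param x state vector `c(theta, theta_dot, theta_ddot)` (rad, rad/s, rad/s^2).
#' @param P 3x3 state covariance.
#' @return object of class `ekf_state`.
#' @export
ekf_state <- function(x, P) {
  P <- (P + t(P)) / 2
  ev <- eigen(P, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-10)) stopf("state covariance is not positive semidefinite")
  structure(list(x = as.numeric(x), P = P), class = "ekf_state")
}

#' Time update (prediction)
#'
#' Propagates the state through the CWPA model: `x <- A x`,
#' `P <- A P A' + Q`.
#'
#' @param state an [ekf_state()].
#' @param cfg an [ekf_config()].
#' @return predicted `ekf_state`.
#' @export
ekf_predict <- function(state, cfg) {
  A <- ekf_process_matrix(cfg$tau)
  Q <- ekf_process_noise(cfg$tau, cfg$q)
  ekf_state(A %*% state$x, A %*% state$P %*% t(A) + Q)
}

#' Measurement update (correction)
#'
#' Kalman gain `K = P H' (H P H' + R)^-1`, innovation correction of the
#' state, covariance update `(I - K H) P` followed by re-symmetrization.
#'
#' @param state predicted `ekf_state`.
#' @param z measurement vector `c(ax, ay, wx)`.
#' @param cfg an [ekf_config()].
#' @return corrected `ekf_state`.
#' @export
ekf_update <- function(state, z, cfg) {
  H <- ekf_measurement_jacobian(state$x, cfg)
  S <- H %*% state$P %*% t(H) + cfg$R
  if (rcond(S) < .Machine$double.eps) {
    stopf("singular innovation covariance in EKF update")
  }
  K <- state$P %*% t(H) %*% solve(S)
  x <- state$x + as.numeric(K %*% (z - ekf_measure(state$x, cfg)))
  P <- (diag(3) - K %*% H) %*% state$P
  ekf_state(x, P)
}

#' Run the EKF over an IMU trial
#'
#' Filters a uniformly sampled IMU trial and returns the estimated angle,
#' angular rate and angular acceleration at every sample. The initial state
#' assumes the trial starts at rest: `theta0 = atan2(-ax, -ay)` from the
#' first accelerometer sample, zero rates. The first returned state is the
#' initial state corrected by the first measurement.
#'
#' @param imu data frame with columns `t` (s), `ax`, `ay` (m/s^2) and
#'   `gx` (rad/s); extra columns are ignored.
#' @param cfg an [ekf_config()]; `cfg$tau` must match the sampling period
#'   within 1%.
#' @param x0 optional initial state vector overriding the static-start
#'   initialization.
#' @return data frame with columns `t`, `theta`, `theta_dot`, `theta_ddot`.
#' @export
run_ekf <- function(imu, cfg = ekf_config(), x0 = NULL) {
  need <- c("t", "ax", "ay", "gx")
  if (!all(need %in% names(imu))) {
    stopf("imu trial must have columns %s", paste(need, collapse = ", "))
  }
  n <- nrow(imu)
  if (n < 2L) stopf("need at least 2 IMU samples")
  dts <- diff(imu$t)
  bad <- which(abs(dts - cfg$tau) > 0.01 * cfg$tau)
  if (length(bad)) {
    stopf("non-uniform sampling: gap of %.5f s at sample %d (expected %.5f s)",
          dts[bad[1]], bad[1], cfg$tau)
  }
  if (is.null(x0)) x0 <- c(atan2(-imu$ax[1], -imu$ay[1]), 0, 0)
  state <- ekf_state(x0, cfg$P0)
  out <- matrix(NA_real_, n, 3)
  state <- ekf_update(state, c(imu$ax[1], imu$ay[1], imu$gx[1]), cfg)
  out[1, ] <- state$x
  for (k in seq_len(n)[-1]) {
    state <- ekf_predict(state, cfg)
    state <- ekf_update(state, c(imu$ax[k], imu$ay[k], imu$gx[k]), cfg)
    out[k, ] <- state$x
  }
  data.frame(t = imu$t, theta = out[, 1], theta_dot = out[, 2],
             theta_ddot = out[, 3])
}
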