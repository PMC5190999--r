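test_that("process matrix and CWPA noise covariance have the stated entries", {
  A <- ekf_process_matrix(0.02)
  expect_equal(A[1, 3], 2e-4)
  expect_equal(A %*% c(0.7, 0, 0), matrix(c(0.7, 0, 0)))
  Q <- ekf_process_noise(1, 1)
  expect_equal(Q[3, 3], 1)
  expect_equal(Q[1, 1], 0.05)
  expect_equal(Q, t(Q))
  expect_equal(ekf_process_noise(0.3, 0), matrix(0, 3, 3))
  expect_error(ekf_process_matrix(0), "positive")
  expect_error(ekf_process_noise(0.1, -1), "nonnegative")
})

test_that("measurement model reproduces gravity, tangential and centripetal terms", {
  cfg <- ekf_config(l = 0.2, g = 9.81)
  expect_equal(ekf_measure(c(0, 0, 0), cfg), c(0, -9.81, 0))
  expect_equal(ekf_measure(c(pi / 2, 0, 0), cfg), c(-9.81, 0, 0),
               tolerance = 1e-12)
  expect_equal(ekf_measure(c(0, 1, 0), cfg), c(0, -9.81 + 0.2, 1))
})

test_that("measurement Jacobian matches central finite differences", {
  cfg <- ekf_config(l = 0.13)
  H0 <- ekf_measurement_jacobian(c(0, 0, 0), cfg)
  expect_equal(H0, matrix(c(-cfg$g, 0, cfg$l, 0, 0, 0, 0, 1, 0),
                          3, byrow = TRUE))
  set.seed(7)
  h <- 1e-6
  for (i in 1:50) {
    x <- c(runif(1, 0, 2.4), runif(1, -3, 3), runif(1, -10, 10))
    H <- ekf_measurement_jacobian(x, cfg)
    Hfd <- sapply(1:3, function(j) {
      dx <- numeric(3)
      dx[j] <- h
      (ekf_measure(x + dx, cfg) - ekf_measure(x - dx, cfg)) / (2 * h)
    })
    expect_equal(H, Hfd, tolerance = 1e-6)
  }
})

test_that("predict and update follow the Kalman equations", {
  cfg <- ekf_config(tau = 0.02, q = 1)
  st <- ekf_state(c(0, 1, 0), diag(c(0.1, 0.1, 1)))
  pred <- ekf_predict(st, cfg)
  expect_equal(pred$x[1], 0.02)
  expect_equal(pred$P, t(pred$P))
  # zero innovation leaves the state untouched
  z <- ekf_measure(pred$x, cfg)
  upd <- ekf_update(pred, z, cfg)
  expect_equal(upd$x, pred$x, tolerance = 1e-12)
  # huge measurement noise: gain ~ 0, state unchanged despite wrong z
  cfg_inf <- ekf_config(tau = 0.02, q = 1, R = diag(3) * 1e12)
  upd2 <- ekf_update(pred, z + c(5, -5, 2), cfg_inf)
  expect_equal(upd2$x, pred$x, tolerance = 1e-6)
})

test_that("measurement update agrees with the information-form MAP solution", {
  # independent route: the linearized posterior mean solves
  # (P^-1 + H' R^-1 H) dx = H' R^-1 innovation
  cfg <- ekf_config(l = 0.18, tau = 0.02, q = 2)
  pred <- ekf_state(c(0.6, 1.2, -0.5),
                    matrix(c(0.2, 0.02, 0, 0.02, 0.3, 0.01, 0, 0.01, 0.8), 3))
  z <- c(-5.2, -8.9, 1.4)
  upd <- ekf_update(pred, z, cfg)
  H <- ekf_measurement_jacobian(pred$x, cfg)
  info <- solve(pred$P) + t(H) %*% solve(cfg$R) %*% H
  dx <- solve(info, t(H) %*% solve(cfg$R) %*% (z - ekf_measure(pred$x, cfg)))
  expect_equal(upd$x, pred$x + as.numeric(dx), tolerance = 1e-9)
  expect_equal(upd$P, solve(info), tolerance = 1e-9)
})

test_that("the filter tracks a noise-free synthetic trial almost exactly", {
  sp <- trial_spec(seed = 3, accel_noise_sd = 1e-12, gyro_noise_sd = 1e-12)
  traj <- generate_trajectory(sp)
  imu <- generate_imu(traj, sp)
  est <- run_ekf(imu)
  expect_lt(nrmsd(traj$theta, est$theta), 1e-3)
})

test_that("covariance stays symmetric positive semidefinite along a run", {
  sp <- trial_spec(seed = 9)
  traj <- generate_trajectory(sp)
  imu <- generate_imu(traj, sp)
  cfg <- ekf_config()
  st <- ekf_state(c(atan2(-imu$ax[1], -imu$ay[1]), 0, 0), cfg$P0)
  for (k in 1:50) {
    st <- ekf_predict(st, cfg)
    st <- ekf_update(st, c(imu$ax[k], imu$ay[k], imu$gx[k]), cfg)
    expect_equal(st$P, t(st$P))
    expect_gte(min(eigen(st$P, symmetric = TRUE, only.values = TRUE)$values),
               -1e-10)
  }
})

test_that("a static trial converges to zero angular rate", {
  n <- 200
  theta0 <- 0.5
  imu <- data.frame(t = seq(0, by = 0.02, length.out = n),
                    ax = -9.81 * sin(theta0), ay = -9.81 * cos(theta0), gx = 0)
  est <- run_ekf(imu)
  expect_lt(abs(est$theta_dot[n]), 1e-6)
  expect_equal(est$theta[n], theta0, tolerance = 1e-6)
})

test_that("sensor fusion beats pure gyro integration under gyro bias", {
  sp <- trial_spec(seed = 12)
  traj <- generate_trajectory(sp)
  imu <- generate_imu(traj, sp)
  imu$gx <- imu$gx + 0.05                      # constant gyroscope bias
  est <- run_ekf(imu)
  gyro_only <- traj$theta[1] + cumsum(imu$gx) * 0.02
  expect_lt(rmse(traj$theta, est$theta), rmse(traj$theta, gyro_only))
})

test_that("non-uniform sampling is rejected with the offending gap", {
  imu <- data.frame(t = c(0, 0.02, 0.05, 0.07), ax = 0, ay = -9.81, gx = 0)
  expect_error(run_ekf(imu), "non-uniform")
})
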