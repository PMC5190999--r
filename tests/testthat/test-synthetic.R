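test_that("the trajectory hits its endpoints with zero boundary derivatives", {
  sp <- trial_spec()
  traj <- generate_trajectory(sp)
  n <- nrow(traj)
  expect_equal(traj$theta[1], sp$theta_min, tolerance = 1e-9)
  expect_equal(traj$theta[n], sp$theta_min, tolerance = 1e-9)
  expect_equal(max(traj$theta), sp$theta_max, tolerance = 1e-9)
  expect_equal(traj$theta[(n + 1) / 2], sp$theta_max, tolerance = 1e-9)
  expect_equal(traj$theta_dot[c(1, n)], c(0, 0))
  expect_equal(traj$theta_ddot[c(1, n)], c(0, 0))
})

test_that("analytic derivatives agree with finite differences on a fine grid", {
  sp <- trial_spec(fs_imu = 2000)
  traj <- generate_trajectory(sp)
  dt <- 1 / sp$fs_imu
  n <- nrow(traj)
  mid <- 2:(n - 1)
  fd <- (traj$theta[mid + 1] - traj$theta[mid - 1]) / (2 * dt)
  keep <- abs(traj$t[mid] - sp$duration / 2) > 2 * dt   # skip the corner
  expect_lt(max(abs(fd[keep] - traj$theta_dot[mid][keep])), 1e-6)
})

test_that("synthetic IMU readings follow the measurement model plus stated noise", {
  sp <- trial_spec(seed = 21)
  traj <- generate_trajectory(sp)
  cfg <- ekf_config()
  imu <- generate_imu(traj, sp, cfg)
  clean_ay <- -cfg$g * cos(traj$theta) + traj$theta_dot^2 * cfg$l
  clean_ax <- -cfg$g * sin(traj$theta) + traj$theta_ddot * cfg$l
  expect_equal(sd(imu$ay - clean_ay), sp$accel_noise_sd, tolerance = 0.1)
  expect_equal(sd(imu$ax - clean_ax), sp$accel_noise_sd, tolerance = 0.1)
  expect_equal(sd(imu$gx - traj$theta_dot), sp$gyro_noise_sd, tolerance = 0.1)
  # same seed, same readings
  expect_identical(generate_imu(traj, sp, cfg), imu)
})

test_that("excitations are bounded bells with flexor/extensor phase separation", {
  sp <- trial_spec(seed = 33)
  traj <- generate_trajectory(sp)
  exc <- generate_excitations(traj, sp)
  expect_true(all(exc$e_true >= 0 & exc$e_true <= 1))
  expect_true(all(exc$e_meas >= 0 & exc$e_meas <= 1))
  for (m in muscle_names("flexor")) {
    expect_lt(traj$t[which.max(exc$e_true[, m])], sp$duration / 2)
  }
  for (m in muscle_names("extensor")) {
    expect_gt(traj$t[which.max(exc$e_true[, m])], sp$duration / 2)
  }
  # zero perturbation leaves the measured excitations equal to the truth
  sp0 <- trial_spec(seed = 33, excitation_perturbation = 0, additive_noise_sd = 0)
  exc0 <- generate_excitations(traj, sp0)
  expect_equal(exc0$e_meas, exc0$e_true)
})

test_that("trials are internally consistent and seed-deterministic", {
  sp <- trial_spec(seed = 13)
  tr <- generate_trial(sp)
  m <- default_model()
  fwd <- forward_moments(tr$theta_true, tr$e_true, m)
  expect_equal(tr$tau_true, fwd$tau)
  expect_equal(tr$forces_true, fwd$forces)
  expect_equal(tr$tau_exp, tr$tau_true)
  tr2 <- generate_trial(trial_spec(seed = 13))
  expect_identical(tr2$imu, tr$imu)
  expect_identical(tr2$e_meas, tr$e_meas)
})

test_that("the perturbation-free pipeline closes on the generating moment", {
  sp <- trial_spec(seed = 6, excitation_perturbation = 0, additive_noise_sd = 0)
  tr <- generate_trial(sp)
  est <- run_ekf(tr$imu)
  fwd <- forward_moments(pmin(pmax(est$theta, 0), 2.4), tr$e_true, default_model())
  expect_lt(nrmsd(tr$tau_true, fwd$tau), 0.01)
})

test_that("trial directories round-trip through plain-text files", {
  tr <- generate_trial(trial_spec(seed = 17))
  dir <- tempfile()
  write_trial_dir(tr, dir)
  tr2 <- read_trial_dir(dir)
  expect_equal(tr2$e_meas, tr$e_meas, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(tr2$tau_exp, tr$tau_exp, tolerance = 1e-9)
  expect_equal(tr2$imu$ax, tr$imu$ax, tolerance = 1e-9)
  expect_equal(tr2$spec$seed, 17)
  unlink(dir, recursive = TRUE)
})
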