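model <- default_model()

test_that("dimensionless curves satisfy their defining identities", {
  cv <- hill_curves()
  expect_equal(force_length_active(1, cv), 1)
  expect_equal(force_length_passive(0.9, cv), 0)
  expect_equal(force_length_passive(1, cv), 0)
  expect_gt(force_length_passive(1.2, cv), 0)
  expect_equal(force_velocity(0, cv), 1)
  v <- seq(-12, 5, by = 0.05)
  expect_true(all(diff(force_velocity(v, cv)) >= 0))
  expect_true(all(force_velocity(v, cv) >= 0))
  expect_lt(force_velocity(100, cv), cv$fv_ecc + 1e-9)
})

test_that("moment arms are the negative angle-derivative of MTU length", {
  thetas <- seq(0.05, 2.35, length.out = 20)
  h <- 1e-5
  for (m in muscle_names()) {
    mus <- model$muscles[[m]]
    kin <- muscle_kinematics(thetas, mus)
    dlmt <- (polyval_asc_test(mus$lmt_poly, thetas + h) -
               polyval_asc_test(mus$lmt_poly, thetas - h)) / (2 * h)
    expect_equal(kin$ma, -dlmt, tolerance = 1e-6)
    # sign convention: flexors positive, extensors negative over the range
    if (mus$role == "flexor") expect_true(all(kin$ma > 0))
    else expect_true(all(kin$ma < 0))
  }
  expect_error(muscle_kinematics(2.6, model$muscles$BIClong), "range")
})

test_that("fiber geometry follows the rigid-tendon pennation model", {
  mus <- list(l0 = 0.1, lts = 0.2, phi0 = 0)
  fg <- fiber_geometry(0.3, mus)
  expect_equal(fg$l_norm, 1)
  expect_equal(fg$phi, 0)
  # constant-thickness identity: at optimal fiber length phi equals phi0
  mus2 <- list(l0 = 0.1, lts = 0.2, phi0 = 0.2)
  fg2 <- fiber_geometry(0.2 + 0.1 * cos(0.2), mus2)
  expect_equal(fg2$l_norm, 1, tolerance = 1e-12)
  expect_equal(fg2$phi, 0.2, tolerance = 1e-12)
  expect_error(fiber_geometry(0.19, mus), "slack")
  # constant MTU length means zero fiber velocity
  fs <- fiber_state_series(rep(0.3, 5), mus, 0.02)
  expect_equal(fs$v_norm, rep(0, 5))
})

test_that("Hill force matches a direct evaluation of the force law", {
  cv <- hill_curves()
  mus <- list(f_max = 500, d_m = 0.1)
  expect_equal(hill_force(1, 0, 0, 1, mus, cv), 500)
  expect_equal(hill_force(0.9, 0, 0, 0, mus, cv), 0)
  # independent spreadsheet-style evaluation at a = 0.5, l = 1.1, v = -0.2
  fa <- exp(-(1.1 - 1)^2 / 0.45)
  fp <- (exp(10 * (1.1 - 1)) - 1) / exp(5)
  fv <- (1 - 0.2 / 10) / (1 + 0.2 / (10 * 0.25))
  expect_equal(hill_force(1.1, -0.2, 0, 0.5, mus, cv),
               500 * (fa * fv * 0.5 + fp + 0.1 * (-0.2)), tolerance = 1e-12)
  # pennation projects by cos(phi)
  expect_equal(hill_force(1, 0, 0.3, 1, mus, cv), 500 * cos(0.3))
  # force cannot be negative (muscles cannot push)
  expect_equal(hill_force(0.9, -0.5, 0, 0, mus, cv), 0)
  # monotone nondecreasing in activation at fixed fiber state
  f <- sapply(seq(0, 1, by = 0.1), function(a) hill_force(1.05, -0.1, 0.1, a, mus, cv))
  expect_true(all(diff(f) >= 0))
})

test_that("joint moment is the signed sum of force times arm", {
  expect_equal(joint_moment(rep(0, 7), rep(0.02, 7)), 0)
  expect_equal(joint_moment(50, 0.02), 1)
  expect_equal(joint_moment(c(50, 20), c(0.02, -0.01)), 0.8)
  expect_error(joint_moment(1:3, 1:2), "length")
})

test_that("inverse dynamics reproduces static gravity moments", {
  limb <- limb_params(mass = 1.5, l_com = 0.18, inertia = 0.06)
  n <- 41
  expect_equal(inverse_dynamics(rep(0, n), limb, 0.02), rep(0, n),
               tolerance = 1e-9)
  expect_equal(inverse_dynamics(rep(pi / 2, n), limb, 0.02),
               rep(1.5 * 9.81 * 0.18, n), tolerance = 1e-9)
  expect_equal(inverse_dynamics(rep(pi / 6, n), limb, 0.02),
               rep(1.3244, n), tolerance = 1e-3)
  expect_error(inverse_dynamics(rep(0, 5), limb, 0.02), "window")
})

test_that("inverse dynamics recovers the moment of a known oscillation", {
  limb <- limb_params(mass = 1.5, l_com = 0.18, inertia = 0.06)
  t <- seq(0, 4, by = 0.02)
  theta <- 0.8 + 0.3 * sin(2 * pi * 0.5 * t)
  theta_dd <- -0.3 * (2 * pi * 0.5)^2 * sin(2 * pi * 0.5 * t)
  tau <- inverse_dynamics(theta, limb, 0.02)
  expected <- limb$inertia * theta_dd + limb$mass * limb$g * limb$l_com * sin(theta)
  mid <- 10:190
  expect_lt(max(abs(tau[mid] - expected[mid])), 0.01)
})

test_that("forward moments from consistent excitations close the loop with inverse dynamics", {
  traj <- generate_trajectory(trial_spec(seed = 5))
  e <- consistent_excitations(traj, model)
  tau_id <- inverse_dynamics(traj$theta, model$limb, 0.02)
  fwd <- forward_moments(traj$theta, e, model)
  expect_lt(nrmsd(tau_id, fwd$tau), 0.02)
})

test_that("passive muscles contribute at most damping-scale moments", {
  traj <- generate_trajectory(trial_spec(seed = 2))
  e0 <- matrix(0, nrow(traj), 7, dimnames = list(NULL, muscle_names()))
  fwd <- forward_moments(traj$theta, e0, model)
  for (m in muscle_names()) {
    mus <- model$muscles[[m]]
    fs <- fiber_state_series(muscle_kinematics(traj$theta, mus)$lmt, mus, 0.02)
    short <- fs$l_norm <= 1
    damping_bound <- mus$f_max * (mus$d_m * abs(fs$v_norm[short]) + 1e-12)
    expect_true(all(fwd$forces[short, m] <= damping_bound))
  }
})

test_that("model YAML serialization round-trips", {
  path <- tempfile(fileext = ".yaml")
  write_model_yaml(model, path)
  m2 <- read_model_yaml(path)
  expect_equal(m2$muscles$BIClong$lmt_poly, model$muscles$BIClong$lmt_poly,
               tolerance = 1e-9)
  expect_equal(m2$muscles$TRIlat$f_max, model$muscles$TRIlat$f_max)
  expect_equal(m2$curves$gamma, model$curves$gamma)
  tr <- generate_trajectory(trial_spec(seed = 1))
  e <- matrix(0.3, nrow(tr), 7, dimnames = list(NULL, muscle_names()))
  expect_equal(forward_moments(tr$theta, e, m2)$tau,
               forward_moments(tr$theta, e, model)$tau, tolerance = 1e-9)
})
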