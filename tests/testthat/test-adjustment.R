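test_that("the single-step solver honours its box and matches a grid oracle", {
  # single-muscle toy with a linear force-excitation map
  tau_lin <- function(e) 10 * e[1]
  # target reachable: exact match, minimal adjustment
  s <- adjust_timestep(0.5, 6, tau_lin, signs = 1, th = 0.5)
  expect_equal(s$tau_hat, 6, tolerance = 1e-8)
  expect_equal(s$e_adj, 0.6, tolerance = 1e-6)
  # target beyond the box: clamps to the nearer box edge
  s2 <- adjust_timestep(0.5, 9, tau_lin, signs = 1, th = 0.2)
  expect_equal(s2$e_adj, 0.6, tolerance = 1e-6)
  # dense grid-search oracle on a two-muscle toy (flexor + extensor)
  tau2 <- function(e) 8 * e[1] - 5 * e[2]
  for (target in c(1.0, 2.5, 4.0)) {
    s3 <- adjust_timestep(c(0.4, 0.3), target, tau2, signs = c(1, -1), th = 0.3)
    grid1 <- seq(0.4 * 0.7, 0.4 * 1.3, length.out = 400)
    grid2 <- seq(0.3 * 0.7, 0.3 * 1.3, length.out = 400)
    oracle <- min(abs(target - outer(8 * grid1, 5 * grid2, "-")))
    # the solver must do at least as well as the dense grid
    expect_lte(abs(target - s3$tau_hat), oracle + 1e-3)
    # box constraint satisfied strictly
    expect_true(all(abs(s3$e_adj - c(0.4, 0.3)) / c(0.4, 0.3) < 0.3))
  }
})

test_that("the unadjusted point is returned when it already meets the target", {
  tau_lin <- function(e) sum(e)
  s <- adjust_timestep(c(0.2, 0.3), 0.5, tau_lin, signs = c(1, 1), th = 0.4)
  expect_equal(s$e_adj, c(0.2, 0.3))
})

test_that("a vanishing tolerance pins the adjustment to the measured excitations", {
  tr <- standard_trial()
  trial <- trial_view(tr)
  res <- adjust_trial(trial, default_model(), th = 1e-6)
  expect_lt(max(abs(res$e_adj - res$e_meas)), 1e-5)
  expect_error(adjust_trial(trial, default_model(), th = 0), "th")
})

test_that("a self-consistent trial needs no adjustment", {
  sp <- trial_spec(seed = 4, excitation_perturbation = 0, additive_noise_sd = 0)
  tr <- generate_trial(sp)
  res <- adjust_trial(trial_view(tr), default_model(), th = 0.3)
  expect_lt(res$moment_nrmsd, 1e-6)
  expect_lt(max(abs(res$e_adj - res$e_meas)), 1e-4)
})

test_that("adjusted excitations respect the relative box and [0, 1] bounds", {
  tr <- standard_trial()
  res <- adjust_trial(trial_view(tr), default_model(), th = 0.5,
                      cfg = adjustment_config(eps_floor = 0.01))
  rel <- abs(res$e_adj - res$e_meas) / pmax(res$e_meas, 0.01)
  expect_lt(max(rel), 0.5)
  expect_true(all(res$e_adj >= 0 & res$e_adj <= 1))
})

test_that("the estimated moment equals the forward chain on the adjusted excitations", {
  tr <- standard_trial()
  m <- default_model()
  res <- adjust_trial(trial_view(tr), m, th = 0.4)
  fwd <- forward_moments(tr$theta_true, res$e_adj, m)
  expect_equal(res$tau_hat, fwd$tau, tolerance = 1e-9)
})

test_that("moment tracking improves with Th and always beats no adjustment", {
  tr <- standard_trial()
  trial <- trial_view(tr)
  m <- default_model()
  unadjusted <- nrmsd(tr$tau_exp, forward_moments(tr$theta_true, tr$e_meas, m)$tau)
  nr <- ex <- numeric(0)
  for (th in c(0.2, 0.5, 0.8)) {
    res <- adjust_trial(trial, m, th)
    expect_lte(res$moment_nrmsd, unadjusted + 1e-9)
    nr <- c(nr, res$moment_nrmsd)
    ex <- c(ex, mean(res$excitation_nrmsd))
  }
  expect_true(all(diff(nr) <= 1e-9))
  expect_true(all(diff(ex) >= -1e-9))
})

test_that("excitation shape is preserved at a wide tolerance", {
  tr <- standard_trial()
  res <- adjust_trial(trial_view(tr), default_model(), th = 0.8)
  expect_true(all(res$excitation_r2 > 0.5))
})

test_that("Th tuning stops at the first tolerance meeting the criterion", {
  tr <- standard_trial()
  trial <- trial_view(tr)
  m <- default_model()
  res <- tune_th(trial, m)
  expect_true(res$criterion_met)
  expect_lte(res$moment_nrmsd, 0.04)
  expect_gte(res$moment_r2, 0.95)
  # unattainable criterion (tiny tolerances cannot absorb a 20% distortion):
  # falls back to the best tolerance, flagged
  res2 <- tune_th(trial, m, adjustment_config(th_start = 0.001, th_step = 0.001,
                                              th_max = 0.003, nrmsd_max = 1e-6))
  expect_false(res2$converged)
  expect_equal(res2$moment_nrmsd,
               min(sapply(c(0.001, 0.002, 0.003), function(th) {
                 adjust_trial(trial, m, th)$moment_nrmsd
               })))
})
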