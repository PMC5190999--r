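## Self-consistent synthetic trial generation: a minimum-jerk
## flexion-extension trajectory, the IMU readings it implies (plus sensor
## noise), bell-shaped flexor/extensor excitation bursts, and ground-truth
## forces and moments from the forward musculotendon chain. Every stage of
## the pipeline can be validated against these trials without any recorded
## data.

#' Synthetic trial specification
#'
#' Defaults emulate the experimental protocol: a slow voluntary elbow
#' flexion from about 10 to about 130 degrees and back, lasting 5.8 s, with
#' the IMU sampled at 50 Hz and excitations at the same working rate. The
#' measured excitations are the true ones distorted by a per-muscle
#' multiplicative amplitude error plus small additive noise (the MVC
#' normalization / cross-talk uncertainty of surface EMG).
#'
#' @param duration trial length (s).
#' @param theta_min,theta_max start/extension and peak flexion angles (rad).
#' @param fs_imu IMU and working sampling rate (Hz).
#' @param accel_noise_sd accelerometer noise SD (m/s^2).
#' @param gyro_noise_sd gyroscope noise SD (rad/s).
#' @param excitation_perturbation relative amplitude distortion applied to
#'   the measured excitations, in `[0, 1)`.
#' @param additive_noise_sd additive excitation noise SD.
#' @param seed RNG seed; trials are byte-identical given spec and seed.
#' @return object of class `trial_spec`.
#' @export
trial_spec <- function(duration = 5.8, theta_min = 10 * pi / 180,
                       theta_max = 130 * pi / 180, fs_imu = 50,
                       accel_noise_sd = 0.2, gyro_noise_sd = 0.02,
                       excitation_perturbation = 0.2,
                       additive_noise_sd = 0.02, seed = 42) {
  if (theta_min >= theta_max) stopf("theta_min must be below theta_max")
  if (duration <= 4 / fs_imu) stopf("duration too short for the sample rate")
  if (excitation_perturbation < 0 || excitation_perturbation >= 1) {
    stopf("excitation perturbation must lie in [0, 1)")
  }
  structure(list(duration = duration, theta_min = theta_min,
                 theta_max = theta_max, fs_imu = fs_imu,
                 accel_noise_sd = accel_noise_sd,
                 gyro_noise_sd = gyro_noise_sd,
                 excitation_perturbation = excitation_perturbation,
                 additive_noise_sd = additive_noise_sd, seed = seed),
            class = "trial_spec")
}

## Minimum-jerk unit profile and its first two derivatives on s in [0, 1].
minjerk <- function(s) 10 * s^3 - 15 * s^4 + 6 * s^5
minjerk_d1 <- function(s) 30 * s^2 - 60 * s^3 + 30 * s^4
minjerk_d2 <- function(s) 60 * s - 180 * s^2 + 120 * s^3

#' Minimum-jerk flexion-extension trajectory
#'
#' Smooth flexion from `theta_min` to `theta_max` over the first half of the
#' trial and extension back over the second half, with zero velocity and
#' acceleration at the boundaries and the midpoint, plus analytic
#' derivatives.
#'
#' @param spec a [trial_spec()].
#' @return data frame with columns `t`, `theta`, `theta_dot`, `theta_ddot`.
#' @export
generate_trajectory <- function(spec) {
  t <- seq(0, spec$duration, by = 1 / spec$fs_imu)
  half <- spec$duration / 2
  amp <- spec$theta_max - spec$theta_min
  s <- ifelse(t <= half, t / half, (t - half) / half)
  up <- t <= half
  theta <- ifelse(up, spec$theta_min + amp * minjerk(s),
                  spec$theta_max - amp * minjerk(s))
  theta_dot <- ifelse(up, amp * minjerk_d1(s) / half,
                      -amp * minjerk_d1(s) / half)
  theta_ddot <- ifelse(up, amp * minjerk_d2(s) / half^2,
                       -amp * minjerk_d2(s) / half^2)
  data.frame(t = t, theta = theta, theta_dot = theta_dot,
             theta_ddot = theta_ddot)
}

#' Synthesize IMU readings from a trajectory
#'
#' Applies the noise-free measurement model ([ekf_measure()]) to the true
#' state at every sample and adds seeded Gaussian sensor noise with the
#' spec's standard deviations.
#'
#' @param traj a trajectory from [generate_trajectory()].
#' @param spec a [trial_spec()].
#' @param cfg an [ekf_config()] supplying the lever arm and gravity.
#' @return data frame with columns `t`, `ax`, `ay`, `gx`.
#' @export
generate_imu <- function(traj, spec, cfg = ekf_config(tau = 1 / spec$fs_imu)) {
  n <- nrow(traj)
  with_seed(spec$seed, {
    ax <- -cfg$g * sin(traj$theta) + traj$theta_ddot * cfg$l +
      stats::rnorm(n, 0, spec$accel_noise_sd)
    ay <- -cfg$g * cos(traj$theta) + traj$theta_dot^2 * cfg$l +
      stats::rnorm(n, 0, spec$accel_noise_sd)
    gx <- traj$theta_dot + stats::rnorm(n, 0, spec$gyro_noise_sd)
    data.frame(t = traj$t, ax = ax, ay = ay, gx = gx)
  })
}

## Default bell peak amplitudes: flexors burst during flexion, extensors
## during extension, peaks within [0.2, 0.6].
default_burst_peaks <- function() {
  c(BIClong = 0.50, BICshort = 0.45, BRA = 0.55, BRD = 0.35,
    TRIlong = 0.40, TRIlat = 0.30, TRImed = 0.35)
}

#' Synthesize true and measured muscle excitations
#'
#' True excitations are Gaussian bells on a small tonic baseline: flexors
#' peak at mid-flexion (one quarter of the trial), extensors at
#' mid-extension (three quarters). Measured excitations are the true ones
#' scaled per muscle by `1 + U(-p, p)` with `p` the spec's perturbation,
#' plus small additive Gaussian noise, clipped to `[0, 1]`.
#'
#' @param traj a trajectory from [generate_trajectory()].
#' @param spec a [trial_spec()].
#' @param peaks named per-muscle bell peak amplitudes.
#' @param width bell standard deviation (s).
#' @param baseline tonic excitation level.
#' @return list with matrices `e_true` and `e_meas` (samples x 7).
#' @export
generate_excitations <- function(traj, spec, peaks = default_burst_peaks(),
                                 width = 0.55, baseline = 0.02) {
  mn <- muscle_names()
  t <- traj$t
  centers <- ifelse(mn %in% muscle_names("flexor"),
                    0.25 * spec$duration, 0.75 * spec$duration)
  e_true <- sapply(seq_along(mn), function(i) {
    clip01(baseline + peaks[[mn[i]]] * exp(-(t - centers[i])^2 / (2 * width^2)))
  })
  colnames(e_true) <- mn
  p <- spec$excitation_perturbation
  e_meas <- with_seed(spec$seed + 1L, {
    gains <- 1 + stats::runif(7, -p, p)
    noise <- matrix(stats::rnorm(length(t) * 7, 0, spec$additive_noise_sd),
                    ncol = 7)
    clip01(sweep(e_true, 2, gains, "*") + if (p > 0 || spec$additive_noise_sd > 0) noise else 0)
  })
  colnames(e_meas) <- mn
  list(e_true = e_true, e_meas = e_meas)
}

#' Generate a complete self-consistent synthetic trial
#'
#' Combines trajectory, IMU synthesis and excitation synthesis, and runs
#' the forward musculotendon chain on the true excitations to obtain the
#' ground-truth muscle forces and joint moment. The trial's experimental
#' moment is that forward-model moment, guaranteeing an internally
#' consistent ground truth for calibration and adjustment experiments.
#'
#' @param spec a [trial_spec()].
#' @param model an `nms_model` (the generating ground-truth model).
#' @param cfg an [ekf_config()] for the IMU synthesis.
#' @return object of class `nms_trial`: `t`, `theta_true` (plus
#'   derivatives), `imu`, `e_true`, `e_meas`, `forces_true`, `tau_true`,
#'   `tau_exp`, `theta` (modelling angle, initialized to the truth; the
#'   pipeline replaces it with the EKF estimate), and the `spec`.
#' @export
generate_trial <- function(spec = trial_spec(), model = default_model(),
                           cfg = ekf_config(tau = 1 / spec$fs_imu)) {
  traj <- generate_trajectory(spec)
  imu <- generate_imu(traj, spec, cfg)
  exc <- generate_excitations(traj, spec)
  fwd <- forward_moments(traj$theta, exc$e_true, model, dt = 1 / spec$fs_imu)
  structure(list(t = traj$t, theta_true = traj$theta,
                 theta_dot_true = traj$theta_dot,
                 theta_ddot_true = traj$theta_ddot, imu = imu,
                 e_true = exc$e_true, e_meas = exc$e_meas,
                 forces_true = fwd$forces, tau_true = fwd$tau,
                 tau_exp = fwd$tau, theta = traj$theta, spec = spec),
            class = "nms_trial")
}

#' @export
print.nms_trial <- function(x, ...) {
  cat(sprintf(paste0("Synthetic elbow trial: %.1f s at %g Hz (%d samples), ",
                     "angle %.0f-%.0f deg, excitation perturbation %.2f, seed %d\n"),
              x$spec$duration, x$spec$fs_imu, length(x$t),
              x$spec$theta_min * 180 / pi, x$spec$theta_max * 180 / pi,
              x$spec$excitation_perturbation, x$spec$seed))
  invisible(x)
}

#' Excitations consistent with the limb's inverse dynamics
#'
#' Solves, sequentially in time, for a common flexor (or extensor) drive on
#' top of a tonic baseline such that the forward musculotendon moment
#' reproduces the inverse-dynamics moment of the trajectory. Used to build
#' trials in which the muscle moments and the rigid-body moments agree
#' (forward/inverse closure).
#'
#' @param traj a trajectory from [generate_trajectory()].
#' @param model an `nms_model`.
#' @param baseline tonic excitation.
#' @return samples x 7 excitation matrix.
#' @export
consistent_excitations <- function(traj, model, baseline = 0.02) {
  dt <- traj$t[2] - traj$t[1]
  tau_id <- inverse_dynamics(traj$theta, model$limb, dt)
  trial <- list(theta = traj$theta,
                e_meas = matrix(baseline, nrow(traj), 7,
                                dimnames = list(NULL, muscle_names())),
                tau_exp = tau_id)
  ws <- adjustment_workspace(trial, model)
  n <- ws$n
  e <- trial$e_meas
  u1 <- u2 <- numeric(7)
  for (t in seq_len(n)) {
    tau_fun <- function(x) {
      u <- ws$alpha * x + ws$b1 * u1 + ws$b2 * u2
      a <- shape_vec(clip01(u), ws$A)
      sum(ws$ma[t, ] * pmax(ws$gact[t, ] * a + ws$goff[t, ], 0))
    }
    ## bisect a single drive level on the side (flexor/extensor) that can
    ## move the moment towards the inverse-dynamics target
    base <- rep(baseline, 7)
    tau0 <- tau_fun(base)
    side <- if (tau_id[t] >= tau0) ws$signs > 0 else ws$signs < 0
    lo <- baseline
    hi <- 1
    for (i in 1:50) {
      mid <- (lo + hi) / 2
      x <- base
      x[side] <- mid
      tau_m <- tau_fun(x)
      toward <- if (tau_id[t] >= tau0) tau_m < tau_id[t] else tau_m > tau_id[t]
      if (toward) lo <- mid else hi <- mid
    }
    x <- base
    x[side] <- (lo + hi) / 2
    idx <- t - ws$d_samp
    keep <- idx >= 1L
    if (any(keep)) e[cbind(idx[keep], which(keep))] <- x[keep]
    u <- ws$alpha * x + ws$b1 * u1 + ws$b2 * u2
    u2 <- u1
    u1 <- u
  }
  e
}
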