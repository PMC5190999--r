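## Plain-text trial input/output used by the command-line interface.

#' Read an IMU trial CSV
#'
#' Expects columns `t`, `ax`, `ay` (m/s^2) and `gx` (rad/s); `az`, `gy`,
#' `gz` may be present and are ignored (single sagittal-plane DOF).
#'
#' @param path CSV file path.
#' @return data frame suitable for [run_ekf()].
#' @export
read_imu_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("t", "ax", "ay", "gx")
  missing_c <- setdiff(need, names(df))
  if (length(missing_c)) {
    stopf("IMU file %s missing column(s): %s", path,
          paste(missing_c, collapse = ", "))
  }
  df
}

#' Read an excitation CSV
#'
#' Expects a `t` column plus one column per model muscle (values in
#' `[0, 1]`), or the three measured channels `BIClong`, `BRD`, `TRIlat`
#' (mapped to all seven muscles with [neural_map()]).
#'
#' @param path CSV file path.
#' @return list with `t` and excitation matrix `e` (samples x 7).
#' @export
read_excitations_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!"t" %in% names(df)) stopf("excitation file %s has no t column", path)
  if (all(muscle_names() %in% names(df))) {
    e <- as.matrix(df[, muscle_names()])
  } else if (all(c("BIClong", "BRD", "TRIlat") %in% names(df))) {
    e <- neural_map(df)
  } else {
    stopf("excitation file %s must contain all 7 muscles or the 3 measured channels", path)
  }
  if (any(e < 0 | e > 1)) stopf("excitations in %s fall outside [0, 1]", path)
  list(t = df$t, e = e)
}

#' Write a synthetic trial to a directory
#'
#' Writes `imu.csv`, `excitations.csv` (measured), and a `truth/`
#' subdirectory with the true angle, excitations, forces and moment, plus a
#' YAML echo of the generating spec.
#'
#' @param trial an `nms_trial`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_trial_dir <- function(trial, dir) {
  dir.create(file.path(dir, "truth"), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(trial$imu, file.path(dir, "imu.csv"), row.names = FALSE)
  utils::write.csv(data.frame(t = trial$t, trial$e_meas, check.names = FALSE),
                   file.path(dir, "excitations.csv"), row.names = FALSE)
  utils::write.csv(data.frame(t = trial$t, theta = trial$theta_true,
                              theta_dot = trial$theta_dot_true,
                              theta_ddot = trial$theta_ddot_true),
                   file.path(dir, "truth", "angle.csv"), row.names = FALSE)
  utils::write.csv(data.frame(t = trial$t, trial$e_true, check.names = FALSE),
                   file.path(dir, "truth", "excitations.csv"), row.names = FALSE)
  utils::write.csv(data.frame(t = trial$t, trial$forces_true, check.names = FALSE),
                   file.path(dir, "truth", "forces.csv"), row.names = FALSE)
  utils::write.csv(data.frame(t = trial$t, tau = trial$tau_true),
                   file.path(dir, "truth", "moment.csv"), row.names = FALSE)
  yaml::write_yaml(unclass(trial$spec), file.path(dir, "spec.yaml"))
  invisible(dir)
}

#' Read a synthetic trial directory
#'
#' @param dir directory written by [write_trial_dir()].
#' @return an `nms_trial`.
#' @export
read_trial_dir <- function(dir) {
  spec <- do.call(trial_spec, yaml::read_yaml(file.path(dir, "spec.yaml")))
  imu <- read_imu_csv(file.path(dir, "imu.csv"))
  exc <- read_excitations_csv(file.path(dir, "excitations.csv"))
  truth_angle <- utils::read.csv(file.path(dir, "truth", "angle.csv"))
  truth_exc <- read_excitations_csv(file.path(dir, "truth", "excitations.csv"))
  truth_forces <- utils::read.csv(file.path(dir, "truth", "forces.csv"))
  truth_tau <- utils::read.csv(file.path(dir, "truth", "moment.csv"))
  structure(list(t = exc$t, theta_true = truth_angle$theta,
                 theta_dot_true = truth_angle$theta_dot,
                 theta_ddot_true = truth_angle$theta_ddot, imu = imu,
                 e_true = truth_exc$e, e_meas = exc$e,
                 forces_true = as.matrix(truth_forces[, muscle_names()]),
                 tau_true = truth_tau$tau, tau_exp = truth_tau$tau,
                 theta = truth_angle$theta, spec = spec),
            class = "nms_trial")
}
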