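## End-to-end orchestration: calibration runs (EKF angle -> activation ->
## Hill chain -> simulated annealing) and simulation runs (Th-tuned
## excitation adjustment, force prediction, synergy comparison).

## Replace the trial's modelling angle with the EKF estimate from its IMU.
ekf_angle_for <- function(trial, ekf_cfg = NULL, use_ekf = TRUE) {
  if (!use_ekf) return(trial)
  if (is.null(ekf_cfg)) ekf_cfg <- ekf_config(tau = 1 / trial$spec$fs_imu)
  est <- run_ekf(trial$imu, ekf_cfg)
  ## stay inside the calibrated kinematic polynomial range
  trial$theta <- pmin(pmax(est$theta, 0), 2.4)
  trial$theta_est <- est
  trial
}

#' Run a calibration
#'
#' Estimates the elbow angle from the trial's IMU with the EKF, then
#' calibrates the model by simulated annealing against the trial's
#' experimental joint moment.
#'
#' @param trial an `nms_trial` (or compatible list with `imu`, `e_meas`,
#'   `tau_exp`).
#' @param model reference `nms_model`.
#' @param spec a [calibration_spec()].
#' @param use_ekf use the EKF angle estimate (`TRUE`, the sensor pipeline)
#'   or the trial's stored angle.
#' @param ekf_cfg optional [ekf_config()].
#' @return list with `model` (calibrated), `calibration`
#'   (`nms_calibration`), `trial` (with the modelling angle used), and
#'   `angle_nrmsd`/`angle_r2` vs the true angle when the trial carries one.
#' @export
run_calibration <- function(trial, model = default_model(),
                            spec = calibration_spec(), use_ekf = TRUE,
                            ekf_cfg = NULL) {
  if (is.null(trial$e_meas)) stopf("trial has no measured excitations")
  missing_m <- setdiff(muscle_names(), colnames(trial$e_meas))
  if (length(missing_m)) {
    stopf("trial excitations missing muscle(s): %s",
          paste(missing_m, collapse = ", "))
  }
  if (is.null(trial$tau_exp)) stopf("trial has no experimental joint moment")
  trial <- ekf_angle_for(trial, ekf_cfg, use_ekf)
  cal <- calibrate_model(trial, model, spec)
  out <- list(model = cal$model, calibration = cal, trial = trial)
  if (!is.null(trial$theta_true) && use_ekf) {
    out$angle_nrmsd <- nrmsd(trial$theta_true, trial$theta_est$theta)
    out$angle_r2 <- r_squared(trial$theta_true, trial$theta_est$theta)
  }
  out
}

#' Run a simulation
#'
#' Estimates the elbow angle with the EKF, adjusts the measured excitations
#' within the tolerance Th (fixed, or tuned by [tune_th()]) so the
#' estimated joint moment tracks the experimental one, predicts the
#' individual muscle forces, and compares the muscle synergies of the
#' measured and adjusted excitations.
#'
#' @param trial an `nms_trial`.
#' @param model calibrated `nms_model`.
#' @param cfg an [adjustment_config()]; set `cfg$th` for a fixed tolerance,
#'   leave `NULL` to tune it.
#' @param k number of synergies for the NMF comparison.
#' @param synergy_seed seed for the NMF restarts.
#' @param use_ekf,ekf_cfg see [run_calibration()].
#' @return list with `adjustment` (`nms_adjustment`), `forces`, `synergy`
#'   (similarities plus both decompositions), `report` (flat named metrics)
#'   and the modelling `trial`.
#' @export
run_simulation <- function(trial, model, cfg = adjustment_config(), k = 2,
                           synergy_seed = 7, use_ekf = TRUE, ekf_cfg = NULL) {
  trial <- ekf_angle_for(trial, ekf_cfg, use_ekf)
  adj <- if (is.null(cfg$th)) tune_th(trial, model, cfg)
         else adjust_trial(trial, model, cfg$th, cfg)
  syn_exp <- extract_synergies(t(adj$e_meas), k = k, seed = synergy_seed)
  syn_adj <- extract_synergies(t(adj$e_adj), k = k, seed = synergy_seed)
  sims <- synergy_similarity(syn_exp, syn_adj)
  report <- c(th_used = adj$th_used, moment_nrmsd = adj$moment_nrmsd,
              moment_r2 = adj$moment_r2,
              stats::setNames(adj$excitation_nrmsd,
                              paste0("excitation_nrmsd_", names(adj$excitation_nrmsd))),
              stats::setNames(adj$excitation_r2,
                              paste0("excitation_r2_", names(adj$excitation_r2))),
              stats::setNames(sims, paste0("synergy_scalar_", seq_along(sims))),
              converged = as.numeric(adj$converged))
  list(adjustment = adj, forces = adj$forces,
       synergy = list(similarity = sims, experimental = syn_exp,
                      adjusted = syn_adj),
       report = report, trial = trial)
}
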