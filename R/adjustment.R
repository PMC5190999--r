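## Simulation-time muscle-excitation adjustment: at every time step the
## excitations feeding the activation filter may deviate from the measured
## ones by at most a relative tolerance Th, and within that box the absolute
## difference between the experimental and estimated joint moment is
## minimized. Includes the Th tuning loop that grows Th from 0.1 in steps of
## 0.1 until the moment fit satisfies the acceptance criterion
## (NRMSD <= 0.04 and R^2 >= 0.95).

#' Adjustment configuration
#'
#' @param th fixed relative excitation tolerance in `(0, 1)`, or `NULL` to
#'   tune it with [tune_th()].
#' @param th_start,th_step,th_max the Th tuning grid.
#' @param nrmsd_max,r2_min acceptance criterion on the moment fit.
#' @param eps_floor floor applied to the denominator of the relative bound,
#'   so near-silent muscles retain a small absolute adjustment band.
#' @return object of class `adjustment_config`.
#' @export
adjustment_config <- function(th = NULL, th_start = 0.1, th_step = 0.1,
                              th_max = 0.9, nrmsd_max = 0.04, r2_min = 0.95,
                              eps_floor = 0.01) {
  if (!is.null(th) && (th <= 0 || th >= 1)) stopf("th must lie in (0, 1)")
  if (nrmsd_max <= 0 || r2_min <= 0 || r2_min >= 1) {
    stopf("invalid acceptance criterion")
  }
  structure(list(th = th, th_start = th_start, th_step = th_step,
                 th_max = th_max, nrmsd_max = nrmsd_max, r2_min = r2_min,
                 eps_floor = eps_floor), class = "adjustment_config")
}

#' Single-step bounded excitation adjustment
#'
#' Minimizes `|target_tau - tau_fun(e_hat)|` over the box
#' `e_hat_i in [e_i - th * max(e_i, eps_floor), e_i + th * max(e_i,
#' eps_floor)]` intersected with `[0, 1]`. The estimated moment is monotone
#' in each excitation (increasing for flexors, decreasing for extensors), so
#' the minimizer lies on the segment from the unadjusted point towards the
#' moment-raising (or -lowering) corner; it is located by bisection. When
#' the target is attainable the solution returned is the attaining point
#' closest to the unadjusted excitations along that segment (smallest
#' adjustment); when it is not, the corner is returned.
#'
#' @param e measured excitations at this time step (length 7, or any length
#'   for toy problems).
#' @param target_tau experimental joint moment to match (N m).
#' @param tau_fun function mapping an excitation vector to the estimated
#'   moment (N m); must be monotone per coordinate with signs `signs`.
#' @param signs per-coordinate monotonicity sign of `tau_fun` (+1 flexor,
#'   -1 extensor).
#' @param th relative tolerance in `(0, 1)`.
#' @param eps_floor relative-bound denominator floor.
#' @param tol bisection tolerance on the moment (N m).
#' @return list with `e_adj` (adjusted excitations) and `tau_hat` (moment
#'   achieved).
#' @export
adjust_timestep <- function(e, target_tau, tau_fun, signs, th,
                            eps_floor = 0.01, tol = 1e-10) {
  if (th <= 0 || th >= 1) stopf("th must lie in (0, 1)")
  ## keep the box strictly inside the open relative constraint |e-ehat|/e < th
  band <- th * pmax(e, eps_floor) * (1 - 1e-9)
  lo <- clip01(e - band)
  hi <- clip01(e + band)
  if (any(lo > hi)) stopf("infeasible adjustment box at coordinate %d", which(lo > hi)[1])
  tau0 <- tau_fun(e)
  if (abs(target_tau - tau0) <= tol) {
    return(list(e_adj = e, tau_hat = tau0))
  }
  corner <- if (target_tau > tau0) ifelse(signs > 0, hi, lo) else ifelse(signs > 0, lo, hi)
  tau1 <- tau_fun(corner)
  ## target beyond the reachable extreme: corner is the constrained optimum
  if ((target_tau > tau0 && tau1 <= target_tau) ||
      (target_tau < tau0 && tau1 >= target_tau)) {
    return(list(e_adj = corner, tau_hat = tau1))
  }
  ## bisect along e + s (corner - e); tau is monotone in s
  s_lo <- 0
  s_hi <- 1
  for (i in 1:60) {
    s <- (s_lo + s_hi) / 2
    cand <- e + s * (corner - e)
    tau_s <- tau_fun(cand)
    if (abs(tau_s - target_tau) <= tol) break
    same_side <- (target_tau > tau0) == (tau_s < target_tau)
    if (same_side) s_lo <- s else s_hi <- s
  }
  cand <- e + s * (corner - e)
  list(e_adj = cand, tau_hat = tau_fun(cand))
}

## Precompute everything the per-step moment evaluation needs: per-muscle
## activation coefficients and the time-indexed force decomposition
## F = max(gact * a + goff, 0), tau = sum(ma * F).
adjustment_workspace <- function(trial, model) {
  mn <- muscle_names()
  n <- length(trial$theta)
  gact <- goff <- mas <- matrix(0, n, 7, dimnames = list(NULL, mn))
  alpha <- b1 <- b2 <- A <- numeric(7)
  d_samp <- integer(7)
  signs <- ifelse(vapply(model$muscles[mn], `[[`, "", "role") == "flexor", 1, -1)
  for (i in seq_along(mn)) {
    mus <- model$muscles[[mn[i]]]
    kin <- muscle_kinematics(trial$theta, mus, model$theta_range)
    fs <- fiber_state_series(kin$lmt, mus, 1 / model$fs)
    scale <- mus$f_max * cos(fs$phi)
    gact[, i] <- scale * force_length_active(fs$l_norm, model$curves) *
      force_velocity(fs$v_norm, model$curves)
    goff[, i] <- scale * (force_length_passive(fs$l_norm, model$curves) +
                            mus$d_m * fs$v_norm)
    mas[, i] <- kin$ma
    p <- activation_params(c1 = mus$act$c1, c2 = mus$act$c2, d = mus$act$d,
                           A = mus$act$A, fs = model$fs)
    alpha[i] <- p$alpha
    b1[i] <- -(p$c1 + p$c2)
    b2[i] <- -(p$c1 * p$c2)
    A[i] <- p$A
    d_samp[i] <- p$d_samples
  }
  list(gact = gact, goff = goff, ma = mas, alpha = alpha, b1 = b1, b2 = b2,
       A = A, d_samp = d_samp, signs = signs, n = n)
}

shape_vec <- function(u, A) {
  ifelse(A == 0, u, expm1(A * u) / expm1(A))
}

#' Adjust the excitations of a whole trial
#'
#' Applies [adjust_timestep()] sequentially over the trial at a fixed Th.
#' The activation-filter memory is carried forward with the adjusted inputs,
#' so each step's moment evaluation is consistent with the adjusted history.
#' The decision variable at step `t` is, for each muscle, the excitation
#' sample that feeds the activation filter at `t` (i.e. the sample delayed
#' by that muscle's electromechanical delay); its box is centred on the
#' corresponding measured sample.
#'
#' @param trial trial list with `theta` (angle series), `e_meas` (samples x
#'   7 measured excitations) and `tau_exp` (experimental moment, N m).
#' @param model calibrated `nms_model`.
#' @param th relative excitation tolerance in `(0, 1)`.
#' @param cfg an [adjustment_config()] (for `eps_floor` and the acceptance
#'   criterion recorded in the result).
#' @return object of class `nms_adjustment`: adjusted excitations `e_adj`,
#'   estimated moment `tau_hat`, muscle `forces`, `th_used`, moment and
#'   per-muscle excitation fit metrics, and `criterion_met`.
#' @export
adjust_trial <- function(trial, model, th, cfg = adjustment_config()) {
  ws <- adjustment_workspace(trial, model)
  mn <- muscle_names()
  e_meas <- trial$e_meas[, mn, drop = FALSE]
  n <- ws$n
  e_adj <- e_meas
  tau_hat <- numeric(n)
  u1 <- u2 <- numeric(7)
  for (t in seq_len(n)) {
    idx <- t - ws$d_samp
    x_meas <- ifelse(idx >= 1L, e_meas[cbind(pmax(idx, 1L), seq_len(7))], 0)
    fixed <- idx < 1L                    # pre-trial silence is not adjustable
    tau_fun <- function(x) {
      u <- ws$alpha * x + ws$b1 * u1 + ws$b2 * u2
      a <- shape_vec(clip01(u), ws$A)
      sum(ws$ma[t, ] * pmax(ws$gact[t, ] * a + ws$goff[t, ], 0))
    }
    if (all(fixed)) {
      x <- x_meas
      tau_t <- tau_fun(x)
    } else {
      sol <- adjust_timestep_masked(x_meas, trial$tau_exp[t], tau_fun,
                                    ws$signs, th, cfg$eps_floor, fixed)
      x <- sol$e_adj
      tau_t <- sol$tau_hat
    }
    keep <- idx >= 1L
    if (any(keep)) e_adj[cbind(idx[keep], which(keep))] <- x[keep]
    u <- ws$alpha * x + ws$b1 * u1 + ws$b2 * u2
    u2 <- u1
    u1 <- u
    tau_hat[t] <- tau_t
  }
  exc_nrmsd <- exc_r2 <- stats::setNames(numeric(7), mn)
  for (i in seq_len(7)) {
    exc_nrmsd[i] <- nrmsd(e_meas[, i], e_adj[, i])
    exc_r2[i] <- r_squared(e_meas[, i], e_adj[, i])
  }
  m_nrmsd <- nrmsd(trial$tau_exp, tau_hat)
  m_r2 <- r_squared(trial$tau_exp, tau_hat)
  fwd <- forward_moments(trial$theta, e_adj, model)
  structure(list(e_adj = e_adj, e_meas = e_meas, tau_hat = tau_hat,
                 tau_exp = trial$tau_exp, forces = fwd$forces,
                 th_used = th, moment_nrmsd = m_nrmsd, moment_r2 = m_r2,
                 excitation_nrmsd = exc_nrmsd, excitation_r2 = exc_r2,
                 criterion_met = m_nrmsd <= cfg$nrmsd_max && m_r2 >= cfg$r2_min,
                 converged = TRUE),
            class = "nms_adjustment")
}

## adjust_timestep with some coordinates frozen (pre-trial silence).
adjust_timestep_masked <- function(e, target_tau, tau_fun, signs, th,
                                   eps_floor, fixed) {
  if (!any(fixed)) {
    return(adjust_timestep(e, target_tau, tau_fun, signs, th, eps_floor))
  }
  free <- !fixed
  wrap <- function(xf) {
    x <- e
    x[free] <- xf
    tau_fun(x)
  }
  sol <- adjust_timestep(e[free], target_tau, wrap, signs[free], th, eps_floor)
  x <- e
  x[free] <- sol$e_adj
  list(e_adj = x, tau_hat = sol$tau_hat)
}

#' @export
print.nms_adjustment <- function(x, ...) {
  cat(sprintf("Excitation adjustment (Th = %.1f): moment NRMSD %.4f, R^2 %.4f%s\n",
              x$th_used, x$moment_nrmsd, x$moment_r2,
              if (x$criterion_met) " [criterion met]" else ""))
  invisible(x)
}

#' Tune the excitation-adjustment tolerance Th
#'
#' Runs [adjust_trial()] at Th = `th_start`, `th_start + th_step`, ... up to
#' `th_max`, and stops at the first Th whose moment fit satisfies
#' `NRMSD <= nrmsd_max` and `R^2 >= r2_min`. If no Th qualifies, the result
#' with the lowest moment NRMSD is returned with `converged = FALSE`.
#'
#' @inheritParams adjust_trial
#' @param cfg an [adjustment_config()].
#' @return an `nms_adjustment` (see [adjust_trial()]).
#' @export
tune_th <- function(trial, model, cfg = adjustment_config()) {
  ths <- seq(cfg$th_start, cfg$th_max + 1e-9, by = cfg$th_step)
  best <- NULL
  for (th in ths) {
    res <- adjust_trial(trial, model, th, cfg)
    if (res$criterion_met) return(res)
    if (is.null(best) || res$moment_nrmsd < best$moment_nrmsd) best <- res
  }
  best$converged <- FALSE
  best
}
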