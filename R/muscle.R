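## Hill-type musculotendon mechanics: dimensionless force-length and
## force-velocity curves, polynomial muscle kinematics (MTU length and
## moment arm vs elbow angle), rigid-tendon fiber state, force generation
## and joint-moment synthesis, plus single-DOF forearm inverse dynamics.

#' Hill-curve parameter set
#'
#' Dimensionless curves of the contractile machinery: Gaussian active
#' force-length `fa = exp(-(l - 1)^2 / gamma)`, exponential passive
#' force-length `fp = (exp(10 (l - 1)) - 1) / e^5` for `l > 1` (zero below
#' optimal length), and a Hill-hyperbola force-velocity curve normalized to
#' `fv(0) = 1` with a C1-continuous eccentric saturation at `fv_ecc`.
#' Velocity is in optimal fiber lengths per second, negative in shortening.
#'
#' @param gamma width of the active force-length Gaussian.
#' @param v_max maximum shortening velocity (optimal lengths / s).
#' @param a_f Hill force-velocity curvature parameter.
#' @param fv_ecc eccentric force plateau (multiple of isometric force).
#' @return object of class `hill_curves`.
#' @export
hill_curves <- function(gamma = 0.45, v_max = 10, a_f = 0.25, fv_ecc = 1.4) {
  ## eccentric exponential rate chosen for slope continuity at v = 0
  k_ecc <- ((1 + 1 / a_f) / v_max) / (fv_ecc - 1)
  structure(list(gamma = gamma, v_max = v_max, a_f = a_f,
                 fv_ecc = fv_ecc, k_ecc = k_ecc), class = "hill_curves")
}

#' Active force-length curve
#' @param l_norm normalized fiber length.
#' @param curves a [hill_curves()].
#' @return dimensionless force scale, 1 at optimal length.
#' @export
force_length_active <- function(l_norm, curves = hill_curves()) {
  exp(-(l_norm - 1)^2 / curves$gamma)
}

#' Passive force-length curve
#' @inheritParams force_length_active
#' @export
force_length_passive <- function(l_norm, curves = hill_curves()) {
  ifelse(l_norm > 1, (exp(10 * (l_norm - 1)) - 1) / exp(5), 0)
}

#' Force-velocity curve
#' @param v_norm normalized fiber velocity (negative shortening).
#' @inheritParams force_length_active
#' @return nondecreasing force scale with `fv(0) = 1`.
#' @export
force_velocity <- function(v_norm, curves = hill_curves()) {
  conc <- pmax(1 + v_norm / curves$v_max, 0) /
    (1 - v_norm / (curves$v_max * curves$a_f))
  ecc <- curves$fv_ecc - (curves$fv_ecc - 1) * exp(-curves$k_ecc * v_norm)
  ifelse(v_norm <= 0, conc, ecc)
}

#' Muscle kinematics from the elbow angle
#'
#' Evaluates a muscle's MTU-length and moment-arm polynomials at the elbow
#' angle. The packaged polynomials are constructed so that the moment arm is
#' exactly the negative derivative of MTU length with respect to the angle.
#' Flexor moment arms are positive, extensor arms negative (flexion-positive
#' sign convention).
#'
#' @param theta elbow angle(s) (rad), within the calibrated range.
#' @param muscle one muscle entry of an [default_model()] (a list with
#'   `lmt_poly` and `ma_poly` ascending polynomial coefficients).
#' @param range valid angle range (rad); no extrapolation outside it.
#' @return list with vectors `lmt` (m) and `ma` (m).
#' @export
muscle_kinematics <- function(theta, muscle, range = c(0, 2.4)) {
  if (any(theta < range[1] - 1e-9 | theta > range[2] + 1e-9)) {
    stopf("angle %.3f rad outside the calibrated kinematic range [%g, %g]",
          theta[which(theta < range[1] | theta > range[2])[1]],
          range[1], range[2])
  }
  list(lmt = polyval_asc(muscle$lmt_poly, theta),
       ma = polyval_asc(muscle$ma_poly, theta))
}

#' Rigid-tendon fiber state
#'
#' With an inextensible tendon of slack length `lts`, the fiber carries the
#' whole MTU length change. Pennation follows the constant-thickness model
#' `l_m sin(phi) = l0 sin(phi0)`, so
#' `l_m = sqrt((lmt - lts)^2 + (l0 sin(phi0))^2)`.
#'
#' @param lmt MTU length(s) (m), must exceed the tendon slack length.
#' @param muscle muscle parameter list with `l0`, `lts`, `phi0`.
#' @return list with `l_norm` (fiber length / optimal length) and `phi`
#'   (current pennation, rad).
#' @export
fiber_geometry <- function(lmt, muscle) {
  la <- lmt - muscle$lts
  if (any(la <= 0)) {
    stopf("MTU length %.4f m does not exceed tendon slack length %.4f m",
          lmt[which(la <= 0)[1]], muscle$lts)
  }
  w <- muscle$l0 * sin(muscle$phi0)
  l_m <- sqrt(la^2 + w^2)
  list(l_norm = l_m / muscle$l0, phi = atan2(w, la))
}

#' Fiber state over a sampled trial
#'
#' Adds the normalized fiber velocity (backward difference of fiber length,
#' zero at the first sample; trials start at rest) to [fiber_geometry()].
#'
#' @inheritParams fiber_geometry
#' @param dt sampling period (s).
#' @return list with `l_norm`, `v_norm`, `phi` vectors.
#' @export
fiber_state_series <- function(lmt, muscle, dt) {
  geom <- fiber_geometry(lmt, muscle)
  l_m <- geom$l_norm * muscle$l0
  v <- c(0, diff(l_m)) / (dt * muscle$l0)
  list(l_norm = geom$l_norm, v_norm = v, phi = geom$phi)
}

#' Hill-type muscle force
#'
#' `F = F_max (fa(l) fv(v) a + fp(l) + d_m v) cos(phi)`, with the bracket
#' floored at zero (muscles cannot push).
#'
#' @param l_norm,v_norm,phi fiber state (vectors or scalars).
#' @param a muscle activation in `[0, 1]`.
#' @param muscle muscle parameter list with `f_max`, `d_m`.
#' @param curves a [hill_curves()].
#' @return muscle force (N), nonnegative.
#' @export
hill_force <- function(l_norm, v_norm, phi, a, muscle, curves = hill_curves()) {
  if (any(a < -1e-12 | a > 1 + 1e-12)) stopf("activation must lie in [0, 1]")
  bracket <- force_length_active(l_norm, curves) * force_velocity(v_norm, curves) * a +
    force_length_passive(l_norm, curves) + muscle$d_m * v_norm
  muscle$f_max * pmax(bracket, 0) * cos(phi)
}

#' Joint moment from muscle forces and moment arms
#'
#' Signed sum of force times moment arm. With flexor arms positive and
#' extensor arms negative this is the net flexion moment.
#'
#' @param forces muscle forces (N): a vector (one instant) or a samples x
#'   muscles matrix.
#' @param arms matching moment arms (m).
#' @return moment (N m), scalar or per-sample vector.
#' @export
joint_moment <- function(forces, arms) {
  if (is.matrix(forces)) {
    if (!all(dim(forces) == dim(arms))) stopf("forces and arms dimensions differ")
    return(rowSums(forces * arms))
  }
  if (length(forces) != length(arms)) stopf("forces and arms lengths differ")
  sum(forces * arms)
}

#' Forearm segment parameters
#'
#' Inertial properties of the forearm-plus-hand segment about the elbow,
#' derived from subject mass and height by standard anthropometric ratios
#' (segment mass 2.2% of body mass; forearm length 14.6% of height; center
#' of mass at 68.2% and radius of gyration at 82.7% of segment length from
#' the elbow). All fields can be overridden.
#'
#' @param body_mass subject mass (kg).
#' @param height subject height (m).
#' @param mass,l_com,inertia,g direct overrides (kg, m, kg m^2, m/s^2).
#' @return object of class `limb_params`.
#' @export
limb_params <- function(body_mass = 68, height = 1.753,
                        mass = NULL, l_com = NULL, inertia = NULL, g = 9.81) {
  L <- 0.146 * height
  if (is.null(mass)) mass <- 0.022 * body_mass
  if (is.null(l_com)) l_com <- 0.682 * L
  if (is.null(inertia)) inertia <- mass * (0.827 * L)^2
  if (mass <= 0 || l_com <= 0 || inertia <= 0 || g <= 0) {
    stopf("limb parameters must all be positive")
  }
  structure(list(mass = mass, l_com = l_com, inertia = inertia, g = g),
            class = "limb_params")
}

#' Single-DOF forearm inverse dynamics
#'
#' Experimental elbow moment of the forearm pendulum:
#' `tau = I theta_ddot + m g l_com sin(theta)`, with the angle measured from
#' vertical so the gravity moment vanishes with the forearm hanging.
#' The angular acceleration is obtained by Savitzky-Golay local-polynomial
#' differentiation of the (possibly noisy) angle series; the smoothed angle
#' from the same fit is used in the gravity term.
#'
#' @param theta uniformly sampled elbow angle series (rad).
#' @param limb a [limb_params()].
#' @param dt sampling period (s).
#' @param window odd Savitzky-Golay window length (samples).
#' @param porder local polynomial order.
#' @return joint-moment series (N m), same length as `theta`.
#' @export
inverse_dynamics <- function(theta, limb, dt, window = 11, porder = 3) {
  if (length(theta) < window) {
    stopf("angle series (%d samples) shorter than the differentiation window (%d)",
          length(theta), window)
  }
  theta_s <- signal::sgolayfilt(theta, p = porder, n = window, m = 0)
  theta_dd <- signal::sgolayfilt(theta, p = porder, n = window, m = 2, ts = dt)
  limb$inertia * theta_dd + limb$mass * limb$g * limb$l_com * sin(theta_s)
}

#' Forward musculotendon chain over a trial
#'
#' Evaluates the full excitation-to-moment chain at the working rate: muscle
#' kinematics at each angle sample, rigid-tendon fiber states, activation
#' dynamics per muscle, Hill forces, and the signed moment sum.
#'
#' @param theta elbow angle series (rad).
#' @param e excitation matrix (samples x 7, columns in [muscle_names()]
#'   order) in `[0, 1]`.
#' @param model an [default_model()]-style model (possibly calibrated).
#' @param dt sampling period (s); defaults to the model working rate.
#' @return list with `tau` (N m series), `forces`, `activations`, `ma`,
#'   `l_norm`, `v_norm` (samples x 7 matrices).
#' @export
forward_moments <- function(theta, e, model, dt = 1 / model$fs) {
  mn <- muscle_names()
  if (is.null(colnames(e))) colnames(e) <- mn
  e <- e[, mn, drop = FALSE]
  n <- length(theta)
  if (nrow(e) != n) stopf("angle and excitation lengths differ (%d vs %d)", n, nrow(e))
  forces <- acts <- mas <- lns <- vns <- matrix(0, n, 7, dimnames = list(NULL, mn))
  for (m in mn) {
    mus <- model$muscles[[m]]
    kin <- muscle_kinematics(theta, mus, model$theta_range)
    fs <- fiber_state_series(kin$lmt, mus, dt)
    p <- activation_params(c1 = mus$act$c1, c2 = mus$act$c2, d = mus$act$d,
                           A = mus$act$A, fs = model$fs)
    a <- activation(e[, m], p)
    forces[, m] <- hill_force(fs$l_norm, fs$v_norm, fs$phi, a, mus, model$curves)
    acts[, m] <- a
    mas[, m] <- kin$ma
    lns[, m] <- fs$l_norm
    vns[, m] <- fs$v_norm
  }
  list(tau = joint_moment(forces, mas), forces = forces, activations = acts,
       ma = mas, l_norm = lns, v_norm = vns)
}
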