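## The packaged seven-muscle elbow model: Hill parameters, activation
## defaults and polynomial muscle kinematics. The values are approximate,
## synthesized to be representative of published upper-limb musculoskeletal
## models; they are not measurements of any individual subject.

## Quadratic flexor moment arm with its peak at theta_peak (rad):
## ma = peak - c (theta - theta_peak)^2, c fixed by the value at theta = 0.
flexor_ma_poly <- function(peak, theta_peak, at_zero) {
  cc <- (peak - at_zero) / theta_peak^2
  c(peak - cc * theta_peak^2, 2 * cc * theta_peak, -cc)
}

## Build one muscle entry from its signed moment-arm polynomial. The
## MTU-length polynomial is the exact antiderivative lmt = C - int(ma), with
## C fixed so the normalized fiber length is 1 at theta_star; that
## construction makes ma = -d(lmt)/d(theta) hold analytically.
make_muscle <- function(name, role, f_max, l0, lts, phi0, d_m, ma_poly, act,
                        theta_star = 1.0) {
  P <- polyint_asc(ma_poly)                      # int(ma), constant term 0
  C <- lts + l0 * cos(phi0) + polyval_asc(P, theta_star)
  lmt_poly <- c(C, 0, 0, 0) - c(P, rep(0, 4 - length(P)))[1:4]
  list(name = name, role = role, f_max = f_max, l0 = l0, lts = lts,
       phi0 = phi0, d_m = d_m, ma_poly = ma_poly, lmt_poly = lmt_poly,
       act = act)
}

#' Packaged seven-muscle elbow model
#'
#' Default musculoskeletal model for elbow flexion-extension: four flexors
#' (BIClong, BICshort, BRA, BRD) and three extensors (TRIlong, TRIlat,
#' TRImed), each with maximum isometric force, optimal fiber length, tendon
#' slack length, pennation, damping, activation-dynamics defaults, and
#' polynomial moment-arm / MTU-length kinematics over the elbow range
#' `[0, 2.4]` rad (0 = forearm hanging vertically, flexion positive).
#' Flexor moment arms are positive quadratics peaking in mid-range;
#' extensor arms are gently varying negatives. Moment-arm and length
#' polynomials are constructed jointly so that `ma = -d(lmt)/d(theta)`
#' holds exactly. All values are approximate, literature-scale defaults
#' intended to be calibrated per subject.
#'
#' @param fs working sampling rate (Hz).
#' @param curves a [hill_curves()] set shared by all muscles.
#' @param limb a [limb_params()] for the forearm segment.
#' @return object of class `nms_model`: list with `muscles` (named list of
#'   7), `curves`, `limb`, `fs`, `theta_range`.
#' @export
default_model <- function(fs = 50, curves = hill_curves(), limb = limb_params()) {
  act0 <- list(c1 = -0.15, c2 = -0.1, d = 0.02, A = -1.5)
  muscles <- list(
    make_muscle("BIClong", "flexor", f_max = 625, l0 = 0.140, lts = 0.270,
                phi0 = 0, d_m = 0.1,
                ma_poly = flexor_ma_poly(0.035, 1.6, 0.013), act = act0),
    make_muscle("BICshort", "flexor", f_max = 435, l0 = 0.135, lts = 0.190,
                phi0 = 0, d_m = 0.1,
                ma_poly = flexor_ma_poly(0.033, 1.6, 0.013), act = act0),
    make_muscle("BRA", "flexor", f_max = 987, l0 = 0.100, lts = 0.054,
                phi0 = 0, d_m = 0.1,
                ma_poly = flexor_ma_poly(0.022, 1.4, 0.010), act = act0),
    make_muscle("BRD", "flexor", f_max = 262, l0 = 0.180, lts = 0.130,
                phi0 = 0, d_m = 0.1,
                ma_poly = flexor_ma_poly(0.045, 1.8, 0.018), act = act0),
    make_muscle("TRIlong", "extensor", f_max = 799, l0 = 0.120, lts = 0.140,
                phi0 = 0.21, d_m = 0.1,
                ma_poly = -c(0.018, 0.004, -0.0012), act = act0),
    make_muscle("TRIlat", "extensor", f_max = 625, l0 = 0.120, lts = 0.098,
                phi0 = 0.16, d_m = 0.1,
                ma_poly = -c(0.017, 0.003, -0.001), act = act0),
    make_muscle("TRImed", "extensor", f_max = 620, l0 = 0.120, lts = 0.091,
                phi0 = 0.16, d_m = 0.1,
                ma_poly = -c(0.016, 0.003, -0.001), act = act0))
  names(muscles) <- vapply(muscles, `[[`, "", "name")
  structure(list(muscles = muscles[muscle_names()], curves = curves,
                 limb = limb, fs = fs, theta_range = c(0, 2.4)),
            class = "nms_model")
}

#' @export
print.nms_model <- function(x, ...) {
  cat(sprintf("Elbow NMS model: %d muscles, working rate %g Hz, angle range [%g, %g] rad\n",
              length(x$muscles), x$fs, x$theta_range[1], x$theta_range[2]))
  df <- do.call(rbind, lapply(x$muscles, function(m) {
    data.frame(muscle = m$name, role = m$role, f_max = m$f_max, l0 = m$l0,
               A = m$act$A, d = m$act$d)
  }))
  rownames(df) <- NULL
  print(df)
  invisible(x)
}

#' Apply group-level calibration parameters to a model
#'
#' Sets per-group activation parameters (`A`, `c1`, `c2`, `d`) and scales
#' maximum isometric forces by per-group factors. Parameter vector layout:
#' `A_flex, c1_flex, c2_flex, d_flex, scale_flex, A_ext, c1_ext, c2_ext,
#' d_ext, scale_ext` (see [calibration_spec()]). Scales are applied to the
#' reference model passed in, so repeated application does not compound.
#'
#' @param model an `nms_model`.
#' @param par named or positional numeric vector of length 10.
#' @return modified `nms_model`.
#' @export
apply_calibration <- function(model, par) {
  par <- as.numeric(par)
  if (length(par) != 10L) stopf("expected 10 calibration parameters, got %d", length(par))
  for (m in names(model$muscles)) {
    off <- if (model$muscles[[m]]$role == "flexor") 0L else 5L
    model$muscles[[m]]$act <- list(c1 = par[off + 2], c2 = par[off + 3],
                                   d = par[off + 4], A = par[off + 1])
    model$muscles[[m]]$f_max <- model$muscles[[m]]$f_max * par[off + 5]
  }
  model
}

#' Write a model to YAML
#'
#' @param model an `nms_model`.
#' @param path output file path.
#' @export
write_model_yaml <- function(model, path) {
  obj <- list(fs = model$fs, theta_range = model$theta_range,
              curves = unclass(model$curves), limb = unclass(model$limb),
              muscles = lapply(model$muscles, unclass))
  yaml::write_yaml(obj, path, precision = 12L)
  invisible(path)
}

#' Read a model from YAML
#'
#' @param path YAML file written by [write_model_yaml()].
#' @return an `nms_model`.
#' @export
read_model_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  muscles <- lapply(obj$muscles, function(m) {
    m$ma_poly <- as.numeric(m$ma_poly)
    m$lmt_poly <- as.numeric(m$lmt_poly)
    m
  })
  structure(list(muscles = muscles[muscle_names()],
                 curves = structure(obj$curves, class = "hill_curves"),
                 limb = structure(obj$limb, class = "limb_params"),
                 fs = obj$fs, theta_range = as.numeric(obj$theta_range)),
            class = "nms_model")
}
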