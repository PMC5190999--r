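## Subject-specific calibration: a seeded global simulated-annealing search
## over group-level activation-dynamics parameters and maximum-force scale
## factors, minimizing the RMSE between the experimental and the
## model-estimated joint moment over a calibration trial. Because the
## objective is a residual sum of squares and the electromechanical delays
## live on the sample grid, the cold end of the schedule is a quench that
## scans the delay grid and polishes the continuous parameters with bounded
## Levenberg-Marquardt least squares (the anneal-then-refine structure of
## modern annealing optimizers).

#' Calibration specification
#'
#' Free parameters (per muscle group, flexors then extensors): nonlinear
#' shape factor `A`, recursive coefficients `c1` and `c2`, electromechanical
#' delay `d` (s, sample-discretized at the working rate), and a
#' maximum-isometric-force scale factor. The budget `max_iters` covers all
#' objective/residual evaluations: random probes, annealing moves, the
#' delay-grid scan and the least-squares polish.
#'
#' @param max_iters total objective-evaluation budget.
#' @param seed RNG seed; runs are deterministic given the seed.
#' @param bounds 2 x 10 matrix (rows lower/upper) overriding the default
#'   parameter bounds.
#' @param cooling geometric cooling factor per temperature stage.
#' @param moves_per_temp proposals evaluated at each temperature.
#' @param n_probes random probes used to set the initial temperature.
#' @param sa_fraction fraction of the budget spent on the annealing phase
#'   (the rest is the quench).
#' @return object of class `calibration_spec`.
#' @export
calibration_spec <- function(max_iters = 5000, seed = 1, bounds = NULL,
                             cooling = 0.8, moves_per_temp = 25,
                             n_probes = 50, sa_fraction = 0.12) {
  if (max_iters < 10) stopf("max_iters must be at least 10")
  if (is.null(bounds)) {
    lower <- c(-3, -0.9, -0.9, 0, 0.5)
    upper <- c(-0.001, 0.9, 0.9, 0.1, 1.5)
    bounds <- rbind(lower = c(lower, lower), upper = c(upper, upper))
  }
  bounds <- as.matrix(bounds)
  if (any(!is.finite(bounds)) || any(bounds[1, ] >= bounds[2, ])) {
    stopf("bounds must be finite with lower < upper")
  }
  colnames(bounds) <- param_names_calibration()
  structure(list(max_iters = max_iters, seed = seed, bounds = bounds,
                 cooling = cooling, moves_per_temp = moves_per_temp,
                 n_probes = n_probes, sa_fraction = sa_fraction),
            class = "calibration_spec")
}

param_names_calibration <- function() {
  as.vector(outer(c("A", "c1", "c2", "d", "fmax_scale"),
                  c("flex", "ext"), paste, sep = "_"))
}

## indices of the sample-discretized delays / continuous parameters
.idx_delay <- c(4L, 9L)
.idx_cont <- setdiff(1:10, c(4L, 9L))

#' Calibration objective
#'
#' Applies a candidate parameter vector to the model, runs the forward
#' excitation-to-moment chain on the trial, and returns the RMSE between the
#' experimental and estimated joint moment. Parameter vectors violating the
#' activation-stability invariants receive a large penalty (1e6) instead of
#' an error, keeping the stochastic search inside a well-defined landscape.
#'
#' @param par numeric vector of length 10 (see [calibration_spec()]).
#' @param trial a trial list with `theta` (angle series used for modelling),
#'   `e_meas` (samples x 7 excitations) and `tau_exp` (N m).
#' @param model reference `nms_model`.
#' @return RMSE (N m), or 1e6 for invalid parameters.
#' @export
calibration_objective <- function(par, trial, model) {
  cs <- par[c(2, 3, 7, 8)]
  if (any(abs(cs) >= 1) || par[1] > 0 || par[6] > 0 ||
      par[1] < -3 || par[6] < -3 || par[4] < 0 || par[9] < 0) {
    return(1e6)
  }
  cand <- apply_calibration(model, par)
  fwd <- forward_moments(trial$theta, trial$e_meas, cand)
  rmse(trial$tau_exp, fwd$tau)
}

#' Calibrate a model by simulated annealing
#'
#' Global phase: bounded, seeded simulated annealing over the 10 group-level
#' parameters (mostly single-coordinate uniform moves whose width shrinks
#' with temperature, occasional small all-coordinate moves, Metropolis
#' acceptance, geometric cooling; delay proposals snapped to the sample
#' grid). Quench phase: every cell of the two-delay sample grid is scanned
#' with a short bounded Levenberg-Marquardt polish of the eight continuous
#' parameters started from the annealed optimum, the best cells are
#' polished to convergence, and a mid-bounds restart at the winning cell
#' guards against a continuous local minimum. The accepted-best trace is
#' nonincreasing and the run is deterministic given `spec$seed`.
#'
#' @param trial calibration trial (see [calibration_objective()]).
#' @param model reference `nms_model`.
#' @param spec a [calibration_spec()].
#' @return object of class `nms_calibration`: list with `best_params`
#'   (named vector), `best_rmse` (N m), `model` (calibrated `nms_model`),
#'   `trace` (accepted-best objective per evaluation), `converged`,
#'   `n_eval`.
#' @export
calibrate_model <- function(trial, model, spec = calibration_spec()) {
  lo <- spec$bounds[1, ]
  hi <- spec$bounds[2, ]
  rng <- hi - lo
  dt <- 1 / model$fs
  n_eval <- 0L
  trace <- numeric(0)
  best_seen <- Inf
  note <- function(v) {
    n_eval <<- n_eval + 1L
    if (v < best_seen) best_seen <<- v
    trace[n_eval] <<- best_seen
    v
  }
  obj <- function(p) note(calibration_objective(p, trial, model))
  resid_fn <- function(p) {
    fwd <- forward_moments(trial$theta, trial$e_meas,
                           apply_calibration(model, p))
    r <- trial$tau_exp - fwd$tau
    note(sqrt(mean(r^2)))
    r
  }
  ## bounded least-squares polish of the continuous parameters at fixed delays
  lm_refine <- function(x, fx, maxiter) {
    wrap <- function(pc) {
      p <- x
      p[.idx_cont] <- pc
      resid_fn(p)
    }
    r <- tryCatch(suppressWarnings(
      minpack.lm::nls.lm(x[.idx_cont], lower = lo[.idx_cont],
                         upper = hi[.idx_cont], fn = wrap,
                         control = minpack.lm::nls.lm.control(maxiter = maxiter))),
      error = function(e) NULL)
    if (is.null(r)) return(list(x = x, f = fx))
    p <- x
    p[.idx_cont] <- r$par
    f <- sqrt(mean(r$fvec^2))
    if (f < fx) list(x = p, f = f) else list(x = x, f = fx)
  }
  snap_d <- function(p) {
    p[.idx_delay] <- pmin(pmax(round(p[.idx_delay] / dt) * dt,
                               lo[.idx_delay]), hi[.idx_delay])
    p
  }
  with_seed(spec$seed, {
    probes <- matrix(stats::runif(spec$n_probes * 10, lo, hi),
                     ncol = 10, byrow = TRUE)
    probes <- t(apply(probes, 1, snap_d))
    pvals <- apply(probes, 1, obj)
    t0 <- stats::sd(pvals[pvals < 1e6])
    if (!is.finite(t0) || t0 <= 0) t0 <- 1
    x <- probes[which.min(pvals), ]
    fx <- min(pvals)
    best_x <- x
    best_f <- fx
    temp <- t0
    sa_budget <- max(spec$n_probes, floor(spec$sa_fraction * spec$max_iters))
    while (n_eval < sa_budget) {
      for (i in seq_len(spec$moves_per_temp)) {
        if (n_eval >= sa_budget) break
        w <- max(temp / t0, 0.001)
        if (stats::runif(1) < 0.15) {
          cand <- pmin(pmax(x + stats::runif(10, -w, w) * rng * 0.3, lo), hi)
        } else {
          j <- sample.int(10, 1)
          cand <- x
          cand[j] <- min(max(x[j] + stats::runif(1, -w, w) * rng[j], lo[j]), hi[j])
        }
        cand <- snap_d(cand)
        fc <- obj(cand)
        if (fc <= fx || stats::runif(1) < exp((fx - fc) / max(temp, 1e-4 * t0))) {
          x <- cand
          fx <- fc
        }
        if (fc < best_f) {
          best_f <- fc
          best_x <- cand
        }
      }
      temp <- temp * spec$cooling
    }
    ## quench: scan the delay grid outward from the annealed cell with a
    ## short polish each, then polish the best cells to convergence
    dgrid_f <- seq(lo[4], hi[4], by = dt)
    dgrid_e <- seq(lo[9], hi[9], by = dt)
    cells <- expand.grid(df = dgrid_f, de = dgrid_e)
    cells <- cells[order(abs(cells$df - best_x[4]) + abs(cells$de - best_x[9])), ]
    cf <- rep(Inf, nrow(cells))
    cx <- vector("list", nrow(cells))
    for (i in seq_len(nrow(cells))) {
      if (n_eval >= floor(0.75 * spec$max_iters)) break
      cand <- best_x
      cand[4] <- cells$df[i]
      cand[9] <- cells$de[i]
      r <- lm_refine(cand, obj(cand), maxiter = 8)
      cf[i] <- r$f
      cx[[i]] <- r$x
    }
    x <- best_x
    fx <- best_f
    for (i in order(cf)[1:2]) {
      if (!is.finite(cf[i]) || n_eval >= spec$max_iters - 100) break
      r <- lm_refine(cx[[i]], cf[i], maxiter = 60)
      if (r$f < fx) {
        x <- r$x
        fx <- r$f
      }
    }
    if (n_eval < spec$max_iters - 100) {
      mid <- snap_d((lo + hi) / 2)
      mid[.idx_delay] <- x[.idx_delay]
      r <- lm_refine(mid, obj(mid), maxiter = 60)
      if (r$f < fx) {
        x <- r$x
        fx <- r$f
      }
    }
    names(x) <- param_names_calibration()
    structure(list(best_params = x, best_rmse = fx,
                   model = apply_calibration(model, x),
                   trace = trace, converged = fx < 1e6,
                   n_eval = n_eval),
              class = "nms_calibration")
  })
}

#' @export
print.nms_calibration <- function(x, ...) {
  cat(sprintf("NMS calibration: best moment RMSE %.4f N m after %d evaluations\n",
              x$best_rmse, x$n_eval))
  print(round(x$best_params, 4))
  invisible(x)
}
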