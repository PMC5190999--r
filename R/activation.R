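## Muscle activation dynamics: excitation-to-activation transformation via a
## second-order discrete recursive filter (the muscle twitch response) with
## electromechanical delay, followed by exponential shaping of the EMG-force
## relationship.

#' Activation-dynamics parameters
#'
#' The recursion is `u(t) = alpha e(t - d) - (c1 + c2) u(t-1) - c1 c2 u(t-2)`.
#' Its poles are `-c1` and `-c2`, so stability requires `|c1| < 1` and
#' `|c2| < 1`. The gain `alpha` is not free: unit steady-state gain (so a
#' sustained full excitation produces full activation) requires
#' `alpha = (1 + c1)(1 + c2)`, and it is derived, not supplied.
#'
#' @param c1,c2 recursive coefficients, each in `(-1, 1)`.
#' @param d electromechanical delay (s); rounded to whole samples at `fs`.
#' @param A nonlinear shape factor in `[-3, 0)`, or 0 for the linear
#'   EMG-force relationship.
#' @param fs working sampling rate (Hz).
#' @return object of class `activation_params` with derived fields `alpha`
#'   and `d_samples`.
#' @export
activation_params <- function(c1 = -0.15, c2 = -0.1, d = 0.02, A = -1.5,
                              fs = 50) {
  if (abs(c1) >= 1 || abs(c2) >= 1) {
    stopf("unstable recursion: |c1| and |c2| must be < 1 (got %.3f, %.3f)", c1, c2)
  }
  if (d < 0) stopf("delay d must be nonnegative")
  if (A > 0 || A < -3) stopf("shape factor A must lie in [-3, 0]")
  alpha <- (1 + c1) * (1 + c2)
  structure(list(c1 = c1, c2 = c2, d = d, A = A, fs = fs,
                 alpha = alpha, d_samples = as.integer(round(d * fs))),
            class = "activation_params")
}

#' Neural activation from excitation
#'
#' Applies the delayed second-order recursion with zero initial conditions
#' (trials start at rest), then clips to `[0, 1]`. The recursion itself is
#' linear; clipping is applied to the finished series so the operator is the
#' exact linear filter whenever the response stays in range.
#'
#' @param e excitation vector in `[0, 1]`.
#' @param p an [activation_params()].
#' @return neural activation vector `u` in `[0, 1]`.
#' @export
neural_activation <- function(e, p) {
  if (p$d_samples >= length(e)) stopf("delay (%d samples) exceeds trial length", p$d_samples)
  x <- p$alpha * delay_samples(e, p$d_samples)
  b1 <- -(p$c1 + p$c2)
  b2 <- -(p$c1 * p$c2)
  u <- as.numeric(stats::filter(x, c(b1, b2), method = "recursive"))
  clip01(u)
}

#' Nonlinear activation shaping
#'
#' `a = (exp(A u) - 1) / (exp(A) - 1)`, a strictly increasing map of
#' `[0, 1]` onto itself. Negative `A` bends the EMG-force relationship
#' upwards at low activation; `A = 0` is the documented continuous linear
#' limit `a = u`.
#'
#' @param u neural activation in `[0, 1]`.
#' @param A shape factor in `[-3, 0]`.
#' @return muscle activation vector `a` in `[0, 1]`.
#' @export
shape_activation <- function(u, A) {
  if (A > 0 || A < -3) stopf("shape factor A must lie in [-3, 0]")
  if (A == 0) return(u)
  expm1(A * u) / expm1(A)
}

#' Excitation to muscle activation
#'
#' Convenience composition of [neural_activation()] and
#' [shape_activation()].
#'
#' @inheritParams neural_activation
#' @return activation vector in `[0, 1]`.
#' @export
activation <- function(e, p) {
  shape_activation(neural_activation(e, p), p$A)
}
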