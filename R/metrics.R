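## Similarity and error metrics used by calibration, excitation adjustment
## and validation.

check_series_pair <- function(reference, estimate) {
  if (!is.numeric(reference) || !is.numeric(estimate)) {
    stopf("both series must be numeric vectors")
  }
  if (length(reference) != length(estimate)) {
    stopf("series lengths differ (%d vs %d)", length(reference), length(estimate))
  }
  if (length(reference) < 2L) stopf("series must have length >= 2")
  if (!all(is.finite(reference)) || !all(is.finite(estimate))) {
    stopf("series contain non-finite values")
  }
  invisible(TRUE)
}

#' Normalized root-mean-square deviation
#'
#' RMS difference between two series divided by the combined range of both
#' series jointly (maximum over the union of both minus the minimum over the
#' union). Symmetric in its arguments; 0 for identical series.
#'
#' @param reference reference series (numeric vector).
#' @param estimate estimated series, same length and units.
#' @return nonnegative scalar.
#' @seealso [rmse()], [r_squared()]
#' @export
nrmsd <- function(reference, estimate) {
  check_series_pair(reference, estimate)
  rng <- max(reference, estimate) - min(reference, estimate)
  if (rng <= 0) {
    stopf("nrmsd is undefined: combined range of the two series is zero")
  }
  sqrt(mean((estimate - reference)^2)) / rng
}

#' Coefficient of determination
#'
#' `1 - SS_res / SS_tot` with the total sum of squares taken about the mean
#' of the reference series. Equals 1 for a perfect fit, 0 for the constant
#' mean predictor, and can be negative for fits worse than the mean.
#'
#' @inheritParams nrmsd
#' @return scalar `<= 1`.
#' @export
r_squared <- function(reference, estimate) {
  check_series_pair(reference, estimate)
  ss_tot <- sum((reference - mean(reference))^2)
  if (ss_tot <= 0) {
    stopf("r_squared is undefined for a constant reference series")
  }
  1 - sum((estimate - reference)^2) / ss_tot
}

#' Root-mean-square error
#'
#' @inheritParams nrmsd
#' @return nonnegative scalar in the units of the inputs.
#' @export
rmse <- function(reference, estimate) {
  check_series_pair(reference, estimate)
  sqrt(mean((estimate - reference)^2))
}
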