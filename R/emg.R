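## Surface-EMG preprocessing: band filtering, rectification, MVC
## normalization, decimation to the motion working rate, and the neural map
## from the three measured channels to the seven model muscles.

## Forward-backward (zero-phase) application of an ARMA filter with odd
## reflect padding at both ends (3x the filter length) to suppress edge
## transients.
zero_phase_filter <- function(flt, x) {
  n <- length(x)
  npad <- 3L * max(length(flt$b), length(flt$a))
  if (n <= npad + 1L) {
    stopf("signal too short (%d samples) for stable zero-phase filtering", n)
  }
  head_pad <- 2 * x[1] - x[(npad + 1L):2L]
  tail_pad <- 2 * x[n] - x[(n - 1L):(n - npad)]
  xp <- c(head_pad, x, tail_pad)
  y <- signal::filter(flt, xp)
  y <- rev(signal::filter(flt, rev(y)))
  y[(npad + 1L):(npad + n)]
}

#' Linear-envelope extraction from raw EMG
#'
#' Standard EMG linear envelope: zero-phase 4th-order Butterworth high-pass
#' at `hp` Hz (removes motion artifact and baseline drift), full-wave
#' rectification, then zero-phase 4th-order Butterworth low-pass at `lp` Hz.
#' Zero phase is realized by forward-backward filtering, so burst timing is
#' preserved. Output is floored at zero.
#'
#' @param x raw EMG channel (mV), uniformly sampled.
#' @param fs sampling rate (Hz), must exceed 60 Hz.
#' @param hp,lp high-pass and low-pass corner frequencies (Hz).
#' @param order Butterworth order of each one-way pass.
#' @return nonnegative envelope vector, same length as `x`.
#' @export
emg_envelope <- function(x, fs, hp = 30, lp = 6, order = 4) {
  if (fs <= 60) stopf("sampling rate must exceed 60 Hz (got %g)", fs)
  bhp <- signal::butter(order, hp / (fs / 2), type = "high")
  blp <- signal::butter(order, lp / (fs / 2), type = "low")
  y <- zero_phase_filter(bhp, x)
  y <- abs(y)
  y <- zero_phase_filter(blp, y)
  pmax(y, 0)
}

#' MVC normalization
#'
#' Divides an envelope by the subject's maximum-voluntary-contraction
#' envelope peak for that channel and clips to `[0, 1]`. True MVC maxima are
#' uncertain, so values above the recorded peak are clipped; the number of
#' clipped samples is attached as attribute `n_clipped`.
#'
#' @param env envelope vector (mV).
#' @param mvc_peak positive MVC envelope peak (mV).
#' @return excitation vector in `[0, 1]`.
#' @export
normalize_mvc <- function(env, mvc_peak) {
  if (!is.numeric(mvc_peak) || length(mvc_peak) != 1L || mvc_peak <= 0) {
    stopf("mvc_peak must be a positive scalar")
  }
  x <- env / mvc_peak
  n_clipped <- sum(x > 1)
  if (n_clipped > 0) {
    warning(sprintf("%d excitation samples exceeded the MVC peak and were clipped",
                    n_clipped), call. = FALSE)
  }
  structure(clip01(x), n_clipped = n_clipped)
}

#' Decimate an envelope to the motion working rate
#'
#' Picks every `fs_from/fs_to`-th sample of an already low-passed envelope
#' (6 Hz content is far below the 25 Hz Nyquist limit of the 50 Hz working
#' rate, so plain decimation is alias-free).
#'
#' @param x envelope or excitation vector at `fs_from`.
#' @param fs_from source rate (Hz).
#' @param fs_to target rate (Hz); must divide `fs_from`.
#' @return vector of length `ceiling(length(x) / (fs_from/fs_to))`.
#' @export
resample_excitation <- function(x, fs_from, fs_to) {
  fac <- fs_from / fs_to
  if (abs(fac - round(fac)) > 1e-9 || fac < 1) {
    stopf("target rate must divide the source rate (factor %.3f)", fac)
  }
  x[seq(1L, length(x), by = as.integer(round(fac)))]
}

#' Map three measured channels onto the seven model muscles
#'
#' Muscles sharing innervation and mechanical action are assumed to share
#' excitation: the short head of biceps and brachialis copy the long head of
#' biceps, and the long and medial triceps heads copy the lateral head.
#' Brachioradialis passes through.
#'
#' @param measured named list, data frame or matrix with columns/elements
#'   `BIClong`, `BRD` and `TRIlat`, each an excitation vector in `[0, 1]`.
#' @return matrix (samples x 7) with columns in [muscle_names()] order.
#' @export
neural_map <- function(measured) {
  need <- c("BIClong", "BRD", "TRIlat")
  if (is.matrix(measured)) measured <- as.data.frame(measured)
  missing_ch <- setdiff(need, names(measured))
  if (length(missing_ch)) {
    stopf("missing measured channel(s): %s", paste(missing_ch, collapse = ", "))
  }
  lens <- vapply(need, function(ch) length(measured[[ch]]), integer(1))
  if (length(unique(lens)) != 1L) stopf("measured channels differ in length")
  out <- cbind(BIClong = measured$BIClong,
               BICshort = measured$BIClong,
               BRA = measured$BIClong,
               BRD = measured$BRD,
               TRIlong = measured$TRIlat,
               TRIlat = measured$TRIlat,
               TRImed = measured$TRIlat)
  out[, muscle_names(), drop = FALSE]
}

#' Full EMG-to-excitation pipeline for one trial
#'
#' Envelope, MVC normalization and decimation for each measured channel,
#' followed by the neural map. The first and last `edge_mask` seconds are
#' flagged in the returned quality mask (zero-phase filter edge region).
#'
#' @param emg data frame with columns `t`, `BIClong`, `BRD`, `TRIlat`
#'   (raw EMG, mV) at `fs_emg`.
#' @param mvc_peaks named numeric vector of MVC envelope peaks (mV) for the
#'   three measured channels.
#' @param fs_emg raw EMG rate (Hz).
#' @param fs_out working rate (Hz).
#' @param edge_mask duration flagged at each end of the trial (s).
#' @return list with `t` (working-rate time), `e` (samples x 7 excitation
#'   matrix) and logical `mask` (TRUE where samples are trustworthy).
#' @export
emg_excitations <- function(emg, mvc_peaks, fs_emg = 1000, fs_out = 50,
                            edge_mask = 0.2) {
  need <- c("BIClong", "BRD", "TRIlat")
  missing_ch <- setdiff(c("t", need), names(emg))
  if (length(missing_ch)) {
    stopf("missing EMG column(s): %s", paste(missing_ch, collapse = ", "))
  }
  meas <- lapply(need, function(ch) {
    if (is.null(mvc_peaks[[ch]])) stopf("missing MVC peak for channel %s", ch)
    env <- emg_envelope(emg[[ch]], fs = fs_emg)
    e <- normalize_mvc(env, mvc_peaks[[ch]])
    resample_excitation(as.numeric(e), fs_emg, fs_out)
  })
  names(meas) <- need
  e <- neural_map(meas)
  t_out <- resample_excitation(emg$t, fs_emg, fs_out)
  mask <- t_out >= (t_out[1] + edge_mask) & t_out <= (t_out[length(t_out)] - edge_mask)
  list(t = t_out, e = e, mask = mask)
}
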