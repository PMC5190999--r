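## Internal helpers shared across modules.

#' Canonical muscle names
#'
#' The seven elbow muscles of the model in canonical order: four flexors
#' (long and short heads of biceps brachii, brachialis, brachioradialis)
#' followed by three extensors (long, lateral and medial heads of triceps
#' brachii).
#'
#' @param role optionally restrict to `"flexor"` or `"extensor"`.
#' @return character vector of muscle names.
#' @export
muscle_names <- function(role = c("all", "flexor", "extensor")) {
  role <- match.arg(role)
  flex <- c("BIClong", "BICshort", "BRA", "BRD")
  ext <- c("TRIlong", "TRIlat", "TRImed")
  switch(role, all = c(flex, ext), flexor = flex, extensor = ext)
}

## Evaluate a polynomial with ascending coefficients c(a0, a1, ...) at x.
polyval_asc <- function(coefs, x) {
  y <- rep(coefs[length(coefs)], length(x))
  if (length(coefs) > 1L) {
    for (i in (length(coefs) - 1L):1L) y <- y * x + coefs[i]
  }
  y
}

## Antiderivative coefficients (ascending), constant term 0.
polyint_asc <- function(coefs) {
  c(0, coefs / seq_along(coefs))
}

## Derivative coefficients (ascending).
polyder_asc <- function(coefs) {
  if (length(coefs) <= 1L) return(0)
  (coefs * (seq_along(coefs) - 1L))[-1L]
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

## Shift a vector right by k samples, zero-filling the head (pure delay).
delay_samples <- function(x, k) {
  n <- length(x)
  if (k <= 0L) return(x)
  if (k >= n) return(rep(0, n))
  c(rep(0, k), x[seq_len(n - k)])
}

## Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
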