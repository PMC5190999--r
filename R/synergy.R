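## Muscle-synergy analysis: non-negative matrix factorization of excitation
## matrices (multiplicative Frobenius updates) and scalar-product similarity
## between synergy sets.

#' Extract muscle synergies by NMF
#'
#' Factorizes a nonnegative muscles x time excitation matrix `E ~ W H` with
#' `W` (muscles x k) the synergy basis and `H` (k x time) the recruitment
#' weights, using multiplicative updates minimizing the Frobenius error.
#' The best of several seeded random restarts is kept; columns of `W` are
#' unit-normalized afterwards with the scale folded into `H`. Deterministic
#' given `seed`.
#'
#' @param E nonnegative matrix, muscles x time (a time x muscles matrix is
#'   transposed automatically when it has [muscle_names()] columns).
#' @param k number of synergies, `1 <= k <= nrow(E)`.
#' @param seed RNG seed.
#' @param iters maximum multiplicative-update iterations per restart.
#' @param restarts seeded random restarts; the lowest-error fit is kept.
#' @param tol relative objective-change convergence tolerance.
#' @return object of class `nms_synergy`: `W` (muscles x k, unit columns),
#'   `H` (k x time), `k`, `recon_error` (Frobenius residual fraction),
#'   `objective` (per-iteration Frobenius error of the winning restart).
#' @export
extract_synergies <- function(E, k = 2, seed = 7, iters = 500, restarts = 5,
                              tol = 1e-8) {
  if (!is.null(colnames(E)) && all(muscle_names() %in% colnames(E)) &&
      ncol(E) == 7 && nrow(E) != 7) {
    E <- t(E[, muscle_names(), drop = FALSE])
  }
  if (any(E < 0)) stopf("excitation matrix must be nonnegative")
  m <- nrow(E)
  if (k < 1 || k > m) stopf("k must lie in [1, %d]", m)
  normE <- sqrt(sum(E^2))
  if (normE == 0) stopf("excitation matrix is identically zero")
  eps <- 1e-12
  best <- NULL
  for (r in seq_len(restarts)) {
    fit <- with_seed(seed + r - 1L, {
      W <- matrix(stats::runif(m * k, 0.1, 1), m, k)
      H <- matrix(stats::runif(k * ncol(E), 0.1, 1), k, ncol(E))
      obj <- numeric(0)
      prev <- Inf
      for (it in seq_len(iters)) {
        H <- H * (t(W) %*% E) / (t(W) %*% W %*% H + eps)
        W <- W * (E %*% t(H)) / (W %*% H %*% t(H) + eps)
        err <- sqrt(sum((E - W %*% H)^2))
        obj <- c(obj, err)
        if (is.finite(prev) && abs(prev - err) <= tol * max(prev, eps)) break
        prev <- err
      }
      list(W = W, H = H, err = err, obj = obj)
    })
    if (is.null(best) || fit$err < best$err) best <- fit
  }
  scale <- sqrt(colSums(best$W^2))
  scale[scale == 0] <- 1
  W <- sweep(best$W, 2, scale, "/")
  H <- sweep(best$H, 1, scale, "*")
  rownames(W) <- rownames(E)
  structure(list(W = W, H = H, k = k, recon_error = best$err / normE,
                 objective = best$obj),
            class = "nms_synergy")
}

#' @export
print.nms_synergy <- function(x, ...) {
  cat(sprintf("Muscle synergies: k = %d, reconstruction residual %.2f%%\n",
              x$k, 100 * x$recon_error))
  print(round(x$W, 3))
  invisible(x)
}

#' Scalar-product similarity between synergy sets
#'
#' Matches the synergy vectors of two decompositions (same muscles, same k)
#' and returns the scalar products of the matched unit vectors. Matching is
#' exhaustive over permutations for `k <= 5` (maximizing the total scalar
#' product), greedy otherwise. For nonnegative unit vectors the products lie
#' in `[0, 1]`.
#'
#' @param a,b `nms_synergy` objects (or matrices with unit-norm columns).
#' @return numeric vector of `k` matched scalar products.
#' @export
synergy_similarity <- function(a, b) {
  Wa <- if (inherits(a, "nms_synergy")) a$W else a
  Wb <- if (inherits(b, "nms_synergy")) b$W else b
  if (!all(dim(Wa) == dim(Wb))) stopf("synergy sets differ in muscles or k")
  Wa <- sweep(Wa, 2, sqrt(colSums(Wa^2)), "/")
  Wb <- sweep(Wb, 2, sqrt(colSums(Wb^2)), "/")
  k <- ncol(Wa)
  S <- t(Wa) %*% Wb
  if (k <= 5) {
    perms <- permutations_of(k)
    tot <- apply(perms, 1, function(p) sum(S[cbind(seq_len(k), p)]))
    p <- perms[which.max(tot), ]
  } else {
    p <- integer(k)
    avail <- seq_len(k)
    for (i in order(apply(S, 1, max), decreasing = TRUE)) {
      j <- avail[which.max(S[i, avail])]
      p[i] <- j
      avail <- setdiff(avail, j)
    }
  }
  S[cbind(seq_len(k), p)]
}

permutations_of <- function(k) {
  if (k == 1) return(matrix(1))
  sub <- permutations_of(k - 1)
  do.call(rbind, lapply(seq_len(k), function(i) {
    cbind(i, matrix(setdiff(seq_len(k), i)[sub], nrow(sub)))
  }))
}
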