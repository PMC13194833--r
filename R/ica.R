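# FastICA with symmetric decorrelation (tanh contrast) and kurtosis/amplitude
# component rejection. The decomposition is square (as many components as
# channels), deterministic given a seed, and back-projection with no rejected
# components inverts the unmixing exactly up to numerical precision.

fastica_sym <- function(X, max_iter = 500, tol = 1e-4, seed = 1L,
                        retries = 10L) {
  # X: channels x samples, assumed roughly zero-mean per channel
  n <- nrow(X); m <- ncol(X)
  Xc <- X - rowMeans(X)
  C <- tcrossprod(Xc) / (m - 1L)
  eg <- eigen(C, symmetric = TRUE)
  if (any(eg$values < 1e-12 * eg$values[1]))
    stop("rank-deficient epoch: whitening impossible")
  Wh <- diag(1 / sqrt(eg$values)) %*% t(eg$vectors)   # whitening
  Dw <- eg$vectors %*% diag(sqrt(eg$values))          # de-whitening
  Z <- Wh %*% Xc

  best <- NULL
  best_delta <- Inf
  for (r in seq_len(retries)) {
    set.seed(seed + r - 1L)
    W <- matrix(stats::rnorm(n * n), n)
    W <- svd_orth(W)
    ok <- FALSE
    for (it in seq_len(max_iter)) {
      WX <- W %*% Z
      G <- tanh(WX)
      gp <- rowMeans(1 - G^2)
      W1 <- tcrossprod(G, Z) / m - diag(gp) %*% W
      W1 <- svd_orth(W1)
      delta <- max(abs(abs(rowSums(W1 * W)) - 1))
      W <- W1
      if (delta < best_delta) { best_delta <- delta; best <- W }
      if (delta < tol) { ok <- TRUE; break }
    }
    if (ok)
      return(list(S = W %*% Z, unmix = W %*% Wh, mix = Dw %*% t(W),
                  center = rowMeans(X), converged = TRUE, seed = seed + r - 1L))
  }
  # No restart converged. With (near-)Gaussian sources the ICA rotation is
  # unidentifiable and the fixed-point iteration cannot settle; any
  # orthogonal rotation is then equally valid, so the best iterate is
  # returned flagged rather than discarded.
  W <- best
  list(S = W %*% Z, unmix = W %*% Wh, mix = Dw %*% t(W),
       center = rowMeans(X), converged = FALSE, delta = best_delta,
       seed = seed)
}

svd_orth <- function(W) {
  s <- svd(W)
  s$u %*% t(s$v)
}

excess_kurtosis <- function(x) {
  x <- x - mean(x)
  m2 <- mean(x^2)
  if (m2 == 0) return(0)
  mean(x^4) / m2^2 - 3
}

#' ICA-based artifact rejection on a single epoch
#'
#' Decomposes the epoch into as many independent components as channels
#' (FastICA, tanh contrast, symmetric decorrelation), flags components whose
#' absolute excess kurtosis exceeds `kurtosis_thresh` or whose peak absolute
#' amplitude exceeds `amp_thresh_sd` component standard deviations, zeroes
#' the flagged components, and back-projects to sensor space. Deterministic
#' given `seed`. On non-convergence the decomposition is retried with fresh
#' initializations; if no restart converges (typical when all sources are
#' near-Gaussian, where the ICA rotation is unidentifiable and component-wise
#' statistics are rotation-stable), the best iterate is used and the result
#' carries `attr(, "ica_converged") = FALSE`, or an error is thrown when
#' `nonconvergence = "error"`.
#'
#' @param ep an `eeg_epoch`.
#' @param kurtosis_thresh absolute excess-kurtosis threshold (default 1.25;
#'   a Gaussian component has excess kurtosis 0).
#' @param amp_thresh_sd peak-amplitude threshold in component SDs
#'   (default 4).
#' @param seed integer seed for the random initialization.
#' @param nonconvergence `"use-best"` (default) or `"error"`.
#' @return The cleaned epoch; the number of rejected components is attached
#'   as the `"ica_rejected"` attribute (with flagged indices in
#'   `"ica_log"` and the convergence flag in `"ica_converged"`).
#' @export
ica_clean <- function(ep, kurtosis_thresh = 1.25, amp_thresh_sd = 4,
                      seed = 1L, nonconvergence = c("use-best", "error")) {
  nonconvergence <- match.arg(nonconvergence)
  X <- ep$data
  if (nrow(X) < 2L) stop("ICA needs at least 2 channels")
  dec <- fastica_sym(X, seed = seed)
  if (!dec$converged && nonconvergence == "error")
    stop(sprintf("FastICA failed to converge (best delta %.3g)", dec$delta))
  S <- dec$S
  kur <- apply(S, 1L, excess_kurtosis)
  sds <- apply(S, 1L, stats::sd)
  peak <- apply(abs(S - rowMeans(S)), 1L, max)
  bad <- which(abs(kur) > kurtosis_thresh | peak > amp_thresh_sd * sds)
  S[bad, ] <- 0
  out <- ep
  out$data <- dec$mix %*% S + dec$center
  dimnames(out$data) <- dimnames(X)
  attr(out, "ica_rejected") <- length(bad)
  attr(out, "ica_log") <- bad
  attr(out, "ica_converged") <- dec$converged
  out
}
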