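# MVAR model fitting by conditional least squares with BIC order selection.
# One lagged Gram matrix is built at the largest candidate order, so every
# candidate is an exact least-squares solution on the same sample window and
# BIC values are comparable across orders.

#' Fit an MVAR model with BIC order selection
#'
#' For each candidate order p in `p_min:p_max`, solves the multichannel
#' least-squares regression of x[t] on its p past values, computes
#' BIC = log det(residual covariance) + log(N)/N * p * n_channels^2, checks
#' stability by the companion-matrix eigenvalue criterion, and returns the
#' stable model minimizing BIC. Unstable candidates are excluded.
#'
#' @param ep an `eeg_epoch` (or a channels x samples matrix).
#' @param p_min,p_max candidate order range (defaults 1 and 30).
#' @return Object of class `mvar_model`: `order`, `coeffs`
#'   (n x n x p array), `noise_cov`, `bic` (vector over candidates, `NA`
#'   where unstable), `stable`, `spectral_radius`, `fs`.
#' @export
fit_mvar <- function(ep, p_min = 1L, p_max = 30L) {
  X <- if (inherits(ep, "eeg_epoch")) ep$data else as.matrix(ep)
  fs <- if (inherits(ep, "eeg_epoch")) ep$fs else NA_real_
  n <- nrow(X); nsamp <- ncol(X)
  if (nsamp <= p_max * n)
    stop("too few samples for the requested maximum order")
  X <- X - rowMeans(X)
  N <- nsamp - p_max                   # common estimation window
  Y <- t(X[, (p_max + 1L):nsamp, drop = FALSE])          # N x n
  Zfull <- matrix(0, N, n * p_max)
  for (k in seq_len(p_max))
    Zfull[, ((k - 1L) * n + 1L):(k * n)] <- t(X[, (p_max + 1L - k):(nsamp - k),
                                                drop = FALSE])
  G <- crossprod(Zfull)                # (np x np) Gram, built once
  Gy <- crossprod(Zfull, Y)
  Syy <- crossprod(Y)

  orders <- p_min:p_max
  bic <- rep(NA_real_, length(orders))
  radii <- rep(NA_real_, length(orders))
  fits <- vector("list", length(orders))
  for (oi in seq_along(orders)) {
    p <- orders[oi]
    idx <- seq_len(n * p)
    B <- tryCatch(solve(G[idx, idx, drop = FALSE], Gy[idx, , drop = FALSE]),
                  error = function(e) NULL)
    if (is.null(B)) next
    A <- array(0, c(n, n, p))
    for (k in seq_len(p))
      A[, , k] <- t(B[((k - 1L) * n + 1L):(k * n), , drop = FALSE])
    Sres <- (Syy - crossprod(Gy[idx, , drop = FALSE], B)) / N
    Sres <- (Sres + t(Sres)) / 2
    ld <- determinant(Sres, logarithm = TRUE)
    if (ld$sign <= 0) next
    radii[oi] <- spectral_radius(A)
    if (radii[oi] >= 1) next           # unstable candidate excluded
    bic[oi] <- as.numeric(ld$modulus) + log(N) / N * p * n^2
    fits[[oi]] <- list(coeffs = A, noise_cov = Sres)
  }
  if (all(is.na(bic)))
    stop(sprintf("no stable MVAR candidate in %d:%d (spectral radii: %s)",
                 p_min, p_max,
                 paste(sprintf("%.3f", radii), collapse = ", ")))
  best <- which.min(bic)
  structure(
    list(order = orders[best], coeffs = fits[[best]]$coeffs,
         noise_cov = fits[[best]]$noise_cov, bic = stats::setNames(bic, orders),
         stable = TRUE, spectral_radius = radii[best], fs = fs),
    class = "mvar_model")
}

#' @export
print.mvar_model <- function(x, ...) {
  cat(sprintf("<mvar_model> order %d (%d channels), BIC %.3f, spectral radius %.3f\n",
              x$order, nrow(x$coeffs), min(x$bic, na.rm = TRUE),
              x$spectral_radius))
  invisible(x)
}

#' Frequency-domain transfer matrix of a fitted MVAR model
#'
#' H(f) = [I - sum_k A_k exp(-i 2 pi f k / fs)]^{-1} evaluated on a
#' frequency grid.
#'
#' @param m an `mvar_model` (or coefficient array).
#' @param freqs frequency grid in Hz (default 0.5-60 Hz in 0.5 Hz steps).
#' @param fs sampling rate in Hz; defaults to the model's.
#' @return Object of class `transfer_matrix`: complex array `H`
#'   (n x n x n_freq) and `freqs`.
#' @export
transfer_matrix <- function(m, freqs = seq(0.5, 60, by = 0.5), fs = NULL) {
  coeffs <- if (inherits(m, "mvar_model")) m$coeffs else m
  if (is.null(fs)) fs <- if (inherits(m, "mvar_model")) m$fs else
    stop("fs required")
  if (inherits(m, "mvar_model") && !isTRUE(m$stable))
    stop("transfer matrix requires a stable model")
  H <- analytic_transfer(coeffs, freqs, fs)
  if (any(!is.finite(Re(H))) || any(!is.finite(Im(H)))) {
    bad <- which(apply(H, 3L, function(h) any(!is.finite(Re(h)))))[1L]
    stop(sprintf("singular spectral matrix at %g Hz", freqs[bad]))
  }
  structure(list(H = H, freqs = freqs), class = "transfer_matrix")
}
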