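#' Artifact subspace reconstruction on a single epoch
#'
#' Estimates a reference channel covariance from the whole epoch and
#' eigendecomposes it. Sliding windows (`window_s` long, `overlap`
#' fractional overlap) are projected into the eigenspace; a window is flagged
#' when its eigenspace variance (mean component variance) exceeds the
#' threshold `mean(eigenvalues) + cutoff * sd(eigenvalues)`. In flagged
#' windows the high-variance components are projected out, but at least
#' `floor(maxdims * n_channels)` dimensions are always retained. Windows are
#' re-assembled by raised-cosine overlap-add, so unflagged stretches pass
#' through unchanged up to numerical precision.
#'
#' @param ep an `eeg_epoch`.
#' @param cutoff threshold in eigenvalue standard deviations (default 5).
#' @param window_s sliding-window length in seconds (default 0.5).
#' @param overlap fractional window overlap (default 0.5).
#' @param maxdims minimum fraction of dimensions to retain when
#'   reconstructing a flagged window (default 0.66).
#' @param mode `"multichannel"` (default; the canonical eigenspace method) or
#'   `"per-channel"`: each channel is screened independently against its own
#'   window-variance distribution and flagged windows are attenuated to the
#'   reference variance, a single-channel adaptation of the same statistical
#'   rule.
#' @return The cleaned epoch; the integer indices of flagged windows are
#'   attached as the `"asr_log"` attribute.
#' @export
asr_clean <- function(ep, cutoff = 5, window_s = 0.5, overlap = 0.5,
                      maxdims = 0.66, mode = c("multichannel", "per-channel")) {
  mode <- match.arg(mode)
  if (mode == "per-channel")
    return(asr_clean_per_channel(ep, cutoff, window_s, overlap))
  X <- ep$data
  nch <- nrow(X); nsamp <- ncol(X)
  wlen <- as.integer(round(window_s * ep$fs))
  if (wlen > nsamp) stop("epoch shorter than one ASR window")
  step <- max(1L, as.integer(round(wlen * (1 - overlap))))

  ctr <- rowMeans(X)
  Xc <- X - ctr
  C <- tcrossprod(Xc) / (nsamp - 1L)
  eg <- eigen(C, symmetric = TRUE)      # decreasing eigenvalues
  V <- eg$vectors
  lam <- eg$values
  thresh <- mean(lam) + cutoff * stats::sd(lam)
  keep_min <- max(1L, floor(maxdims * nch))

  starts <- seq(1L, max(1L, nsamp - wlen + 1L), by = step)
  if (starts[length(starts)] + wlen - 1L < nsamp)
    starts <- c(starts, nsamp - wlen + 1L)
  # raised-cosine analysis window; accumulate weighted windows and weights
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(wlen) - 0.5) / wlen)
  acc <- matrix(0, nch, nsamp)
  wacc <- numeric(nsamp)
  flagged <- integer(0)
  for (k in seq_along(starts)) {
    idx <- starts[k]:(starts[k] + wlen - 1L)
    seg <- Xc[, idx, drop = FALSE]
    Y <- crossprod(V, seg)              # eigenspace coordinates
    v <- rowSums(Y^2) / (wlen - 1L)
    if (mean(v) > thresh) {             # window variance in eigenspace
      flagged <- c(flagged, k)
      max_remove <- nch - keep_min
      bad <- which(v > thresh)
      if (!length(bad)) bad <- which.max(v)
      if (length(bad) > max_remove)
        bad <- order(v, decreasing = TRUE)[seq_len(max_remove)]
      Y[bad, ] <- 0
      seg <- V %*% Y
    }
    acc[, idx] <- acc[, idx] + sweep(seg, 2L, w, `*`)
    wacc[idx] <- wacc[idx] + w
  }
  out <- ep
  out$data <- sweep(acc, 2L, wacc, `/`) + ctr
  attr(out, "asr_log") <- flagged
  out
}

# single-channel variant: window variances are screened against the channel's
# own variance distribution (robust location/scale so a burst cannot mask
# itself); flagged windows are rescaled to the reference SD
asr_clean_per_channel <- function(ep, cutoff, window_s, overlap) {
  X <- ep$data
  nsamp <- ncol(X)
  wlen <- as.integer(round(window_s * ep$fs))
  if (wlen > nsamp) stop("epoch shorter than one ASR window")
  step <- max(1L, as.integer(round(wlen * (1 - overlap))))
  starts <- seq(1L, max(1L, nsamp - wlen + 1L), by = step)
  if (starts[length(starts)] + wlen - 1L < nsamp)
    starts <- c(starts, nsamp - wlen + 1L)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(wlen) - 0.5) / wlen)
  flagged <- list()
  out <- ep
  for (ch in seq_len(nrow(X))) {
    x <- X[ch, ] - mean(X[ch, ])
    v <- vapply(starts, function(s) stats::var(x[s:(s + wlen - 1L)]), 0)
    thresh <- stats::median(v) + cutoff * stats::mad(v)
    bad <- which(v > thresh)
    acc <- numeric(nsamp); wacc <- numeric(nsamp)
    ref_sd <- sqrt(mean(v[setdiff(seq_along(v), bad)]))
    for (k in seq_along(starts)) {
      idx <- starts[k]:(starts[k] + wlen - 1L)
      seg <- x[idx]
      if (k %in% bad && stats::sd(seg) > 0)
        seg <- seg * ref_sd / stats::sd(seg)
      acc[idx] <- acc[idx] + seg * w
      wacc[idx] <- wacc[idx] + w
    }
    out$data[ch, ] <- acc / wacc + mean(X[ch, ])
    if (length(bad)) {
      nm <- if (is.null(rownames(X))) paste0("ch", ch) else rownames(X)[ch]
      flagged[[nm]] <- bad
    }
  }
  attr(out, "asr_log") <- flagged
  out
}
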