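# The three connectivity estimators: DTF from the MVAR transfer matrix, and
# iCOH / wPLI from Welch-segment cross-spectra. Band values are arithmetic
# means over frequency bins in the half-open interval [lo, hi).

conn_matrix <- function(W, directed, measure, band, epoch = NA_integer_) {
  structure(list(W = W, directed = directed, measure = measure,
                 band = band, epoch = epoch),
            class = "conn_matrix")
}

#' @export
print.conn_matrix <- function(x, ...) {
  cat(sprintf("<conn_matrix> %s (%s), band %s, %d x %d, range [%.3f, %.3f]\n",
              x$measure, if (x$directed) "directed" else "symmetric",
              x$band, nrow(x$W), ncol(x$W), min(x$W), max(x$W)))
  invisible(x)
}

band_bins <- function(freqs, band) {
  band <- band_row(band)
  sel <- freqs >= band$lo & freqs < band$hi
  if (!any(sel)) stop(sprintf("band %s outside the frequency grid", band$name))
  sel
}

#' Directed transfer function from a transfer matrix
#'
#' Per frequency bin, `DTF[j -> i](f) = |H_ij(f)|^2 / sum_k |H_ik(f)|^2`
#' (normalization over all sources k flowing into sink i), then averaged
#' over the band's bins. By construction the inflow into every sink sums to
#' 1 at every bin, so values lie in `[0, 1]`. The `W[i, j]` entry is the
#' influence of source channel j on sink channel i; the diagonal is retained
#' by the formula and excluded later at the network-construction stage.
#'
#' @param H a `transfer_matrix`.
#' @param band band name or definition (see [eeg_bands()]).
#' @return A `conn_matrix` (directed).
#' @export
dtf <- function(H, band = "full") {
  stopifnot(inherits(H, "transfer_matrix"))
  sel <- which(band_bins(H$freqs, band))
  n <- dim(H$H)[1L]
  acc <- matrix(0, n, n)
  for (b in sel) {
    P <- Mod(H$H[, , b])^2
    rs <- rowSums(P)
    if (any(rs == 0)) stop("all-zero transfer row: DTF undefined")
    acc <- acc + P / rs
  }
  conn_matrix(acc / length(sel), directed = TRUE, measure = "DTF",
              band = band_row(band)$name)
}

#' Welch-segment cross-spectral density of an epoch
#'
#' Hann-windowed, overlapping segments; per-segment cross-spectra are
#' averaged into a Hermitian channels x channels x frequency array with
#' one-sided power normalization (so the integral of an auto-spectrum over
#' frequency approximates the channel variance). Per-segment terms are kept
#' for the wPLI estimator.
#'
#' @param ep an `eeg_epoch`.
#' @param seg_s segment length in seconds (default 1).
#' @param overlap fractional overlap (default 0.5).
#' @param keep_segments keep per-segment cross-spectra (default TRUE;
#'   required by [wpli()]).
#' @return Object of class `cross_spectrum`: `S` (averaged), `S_seg`
#'   (optional, ch x ch x freq x segment), `freqs`, `n_segments`.
#' @export
cross_spectrum <- function(ep, seg_s = 1, overlap = 0.5, keep_segments = TRUE) {
  X <- ep$data
  fs <- ep$fs
  n <- nrow(X); nsamp <- ncol(X)
  slen <- as.integer(round(seg_s * fs))
  step <- max(1L, as.integer(round(slen * (1 - overlap))))
  if (slen + step > nsamp)
    stop("need at least 2 Welch segments (epoch too short for seg_s/overlap)")
  starts <- seq(1L, nsamp - slen + 1L, by = step)
  if (length(starts) < 2L)
    stop("need at least 2 Welch segments (epoch too short for seg_s/overlap)")
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(slen) - 1L) / (slen - 1L))
  U <- fs * sum(w^2)                    # one-sided PSD normalization
  nf <- slen %/% 2L + 1L
  freqs <- (seq_len(nf) - 1L) * fs / slen
  X <- X - rowMeans(X)

  nseg <- length(starts)
  Sseg <- array(complex(real = 0), c(n, n, nf, nseg))
  for (si in seq_len(nseg)) {
    seg <- X[, starts[si]:(starts[si] + slen - 1L), drop = FALSE]
    seg <- sweep(seg, 2L, w, `*`)
    Z <- t(stats::mvfft(t(seg)))[, seq_len(nf), drop = FALSE]
    for (f in seq_len(nf)) {
      cs <- Z[, f] %o% Conj(Z[, f]) / U
      if (f > 1L && (slen %% 2L == 1L || f < nf)) cs <- 2 * cs
      Sseg[, , f, si] <- cs
    }
  }
  S <- rowMeans(Sseg, dims = 3L)
  structure(list(S = S, S_seg = if (keep_segments) Sseg else NULL,
                 freqs = freqs, n_segments = nseg),
            class = "cross_spectrum")
}

#' @export
print.cross_spectrum <- function(x, ...) {
  cat(sprintf("<cross_spectrum> %d channels, %d bins (0-%g Hz), %d segments\n",
              dim(x$S)[1L], length(x$freqs), max(x$freqs), x$n_segments))
  invisible(x)
}

#' Imaginary part of coherency
#'
#' Per bin, `iCOH_ij(f) = Im(S_ij / sqrt(S_ii S_jj))`; the band value is the
#' mean of `|Im COH|` over the band's bins. Insensitive to zero-lag
#' (volume-conducted) coupling, which leaves the coherency real.
#'
#' @param S a `cross_spectrum`.
#' @param band band name or definition.
#' @return A `conn_matrix` (symmetric, zero diagonal).
#' @export
icoh <- function(S, band = "full") {
  stopifnot(inherits(S, "cross_spectrum"))
  sel <- which(band_bins(S$freqs, band))
  n <- dim(S$S)[1L]
  acc <- matrix(0, n, n)
  for (b in sel) {
    Sb <- S$S[, , b]
    auto <- Re(diag(Sb))
    if (any(auto <= 0)) stop("zero auto-spectrum: coherency undefined")
    acc <- acc + abs(Im(Sb / sqrt(auto %o% auto)))
  }
  W <- acc / length(sel)
  diag(W) <- 0
  W <- (W + t(W)) / 2
  conn_matrix(W, directed = FALSE, measure = "iCOH", band = band_row(band)$name)
}

#' Coherence magnitude (for volume-conduction contrast checks)
#'
#' Band-mean of `|S_ij| / sqrt(S_ii S_jj)` from the segment-averaged
#' cross-spectrum. Provided for comparison with [icoh()] and [wpli()]:
#' unlike them, it is inflated by zero-lag mixing.
#'
#' @inheritParams icoh
#' @return A `conn_matrix` (symmetric, zero diagonal).
#' @export
coherence <- function(S, band = "full") {
  stopifnot(inherits(S, "cross_spectrum"))
  sel <- which(band_bins(S$freqs, band))
  n <- dim(S$S)[1L]
  acc <- matrix(0, n, n)
  for (b in sel) {
    Sb <- S$S[, , b]
    auto <- Re(diag(Sb))
    if (any(auto <= 0)) stop("zero auto-spectrum: coherence undefined")
    acc <- acc + Mod(Sb) / sqrt(auto %o% auto)
  }
  W <- acc / length(sel)
  diag(W) <- 0
  conn_matrix(W, directed = FALSE, measure = "COH", band = band_row(band)$name)
}

#' Weighted phase lag index
#'
#' Per bin, `wPLI_ij = |mean_seg Im(S_ij)| / mean_seg |Im(S_ij)|`, the
#' expectation running over Welch segments within the epoch, then
#' band-averaged. Pairs whose imaginary cross-spectrum vanishes in every
#' segment are defined as 0. The debiased variant replaces the ratio with
#' the debiased squared estimator.
#'
#' @param S a `cross_spectrum` computed with `keep_segments = TRUE`.
#' @param band band name or definition.
#' @param debias use the debiased squared-wPLI estimator (default FALSE).
#' @return A `conn_matrix` (symmetric, zero diagonal, values in `[0, 1]`).
#' @export
wpli <- function(S, band = "full", debias = FALSE) {
  stopifnot(inherits(S, "cross_spectrum"))
  if (is.null(S$S_seg)) stop("wPLI needs per-segment cross-spectra")
  if (S$n_segments < 2L) stop("wPLI needs at least 2 segments")
  sel <- which(band_bins(S$freqs, band))
  n <- dim(S$S_seg)[1L]
  acc <- matrix(0, n, n)
  for (b in sel) {
    I <- Im(S$S_seg[, , b, ])           # n x n x nseg
    num <- abs(apply(I, c(1, 2), mean))
    den <- apply(abs(I), c(1, 2), mean)
    if (debias) {
      ns <- S$n_segments
      sum_i <- apply(I, c(1, 2), sum)
      sum_i2 <- apply(I^2, c(1, 2), sum)
      den2 <- apply(abs(I), c(1, 2), sum)^2 - sum_i2
      v <- (sum_i^2 - sum_i2) / ifelse(den2 == 0, 1, den2)
      v[den2 == 0] <- 0
      acc <- acc + pmax(v, 0)
    } else {
      v <- num / ifelse(den == 0, 1, den)
      v[den == 0] <- 0
      acc <- acc + v
    }
  }
  W <- acc / length(sel)
  diag(W) <- 0
  W <- (W + t(W)) / 2
  conn_matrix(W, directed = FALSE, measure = "wPLI", band = band_row(band)$name)
}
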