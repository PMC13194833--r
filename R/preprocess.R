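# Epoching and the fixed filter chain: 50 Hz notch, 60-100 Hz Butterworth
# band-stop, linear-phase FIR band-pass at the analysis band edges. IIR stages
# are applied forward-backward (zero phase); the FIR is symmetric (linear
# phase) and also applied with filtfilt so epochs stay time-aligned.

#' Canonical EEG frequency bands
#'
#' delta 0.5-4, theta 4-8, alpha 8-13, beta 13-30, gamma 30-60 and full
#' 0.5-60 Hz. Band intervals are treated as half-open `[lo, hi)` wherever
#' frequency bins are aggregated, so adjacent bands do not share bins.
#'
#' @param names optional subset of band names to return.
#' @return data.frame with columns `name`, `lo`, `hi`.
#' @export
eeg_bands <- function(names = NULL) {
  b <- data.frame(
    name = c("delta", "theta", "alpha", "beta", "gamma", "full"),
    lo = c(0.5, 4, 8, 13, 30, 0.5),
    hi = c(4, 8, 13, 30, 60, 60),
    stringsAsFactors = FALSE)
  if (!is.null(names)) {
    if (!all(names %in% b$name)) stop("unknown band name")
    b <- b[match(names, b$name), , drop = FALSE]
  }
  b
}

band_row <- function(band) {
  if (is.character(band)) band <- eeg_bands(band)
  stopifnot(is.data.frame(band), nrow(band) == 1L, band$lo > 0, band$lo < band$hi)
  band
}

#' Cut a recording into non-overlapping epochs
#'
#' Discards the first `discard_s` seconds, then returns
#' `floor(analysis_s / epoch_s)` contiguous non-overlapping epochs with
#' sample-exact boundaries. Defaults reproduce the study design: discard
#' 10 s, analyze 240 s as 40 epochs of 6 s.
#'
#' @param rec an [eeg_recording()].
#' @param discard_s initial seconds to discard (default 10).
#' @param epoch_s epoch length in seconds (default 6).
#' @param analysis_s analysis window length in seconds (default 240).
#' @return List of `eeg_epoch` objects (channels x samples matrices with
#'   `fs`, `index` and parent metadata).
#' @export
epoch_recording <- function(rec, discard_s = 10, epoch_s = 6, analysis_s = 240) {
  fs <- rec$fs
  need <- discard_s + analysis_s
  have <- n_samples(rec) / fs
  if (have < need - 1e-9)
    stop(sprintf("recording too short: %.1f s available, %.1f s required (discard %g s + analysis %g s)",
                 have, need, discard_s, analysis_s))
  n_ep <- floor(analysis_s / epoch_s + 1e-9)
  len <- as.integer(round(epoch_s * fs))
  off <- as.integer(round(discard_s * fs))
  lapply(seq_len(n_ep), function(i) {
    idx <- (off + (i - 1L) * len + 1L):(off + i * len)
    structure(
      list(data = rec$data[, idx, drop = FALSE], fs = fs, index = i,
           band = NA_character_, subject_id = rec$subject_id,
           group = rec$group, state = rec$state),
      class = "eeg_epoch")
  })
}

#' @export
print.eeg_epoch <- function(x, ...) {
  cat(sprintf("<eeg_epoch #%d> %d channels x %d samples @ %g Hz, band %s (%s %s %s)\n",
              x$index, nrow(x$data), ncol(x$data), x$fs, x$band,
              x$subject_id, x$group, x$state))
  invisible(x)
}

# RBJ biquad notch at f0 with quality factor Q
notch_biquad <- function(f0, fs, Q = 35) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  signal::Arma(b = b / a[1], a = a / a[1])
}

# Linear-phase FIR band-pass via windowed design; the order follows the
# Kaiser rule for the target stop-band attenuation (80 dB, i.e. ripple 1e-4)
# and a transition width of 25% of the lower edge, at least 1 Hz.
design_fir_bandpass <- function(lo, hi, fs) {
  trans <- max(1, 0.25 * lo)
  atten_db <- 80
  n_taps <- ceiling((atten_db - 7.95) / (2.285 * 2 * pi * trans / fs))
  n_taps <- min(n_taps, 2001L)
  if (n_taps %% 2L == 0L) n_taps <- n_taps + 1L
  nyq <- fs / 2
  hi_edge <- min(hi, nyq * 0.99)
  beta <- 0.1102 * (atten_db - 8.7)
  as.numeric(signal::fir1(n_taps - 1L, c(lo, hi_edge) / nyq, type = "pass",
                          window = signal::kaiser(n_taps, beta)))
}

# zero-phase IIR filtering with edge padding (odd-symmetric reflection) so
# short epochs are not dominated by filter start-up transients
zp_filter <- function(filt, x, pad) {
  n <- length(x)
  pad <- min(pad, n - 1L)
  left <- 2 * x[1] - x[(pad + 1L):2L]
  right <- 2 * x[n] - x[(n - 1L):(n - pad)]
  y <- signal::filtfilt(filt, c(left, x, right))
  y[(pad + 1L):(pad + n)]
}

# single-pass linear-phase FIR via FFT convolution with group-delay
# compensation; reflection padding keeps edges usable on 6-s epochs
fir_apply <- function(h, x) {
  n <- length(x); m <- length(h)
  delay <- (m - 1L) %/% 2L
  pad <- min(delay, n - 1L)
  left <- 2 * x[1] - x[(pad + 1L):2L]
  right <- 2 * x[n] - x[(n - 1L):(n - pad)]
  xp <- c(left, x, right)
  L <- stats::nextn(length(xp) + m - 1L, 2)
  y <- Re(stats::fft(stats::fft(c(xp, rep(0, L - length(xp)))) *
                     stats::fft(c(h, rep(0, L - m))), inverse = TRUE)) / L
  y[(pad + delay + 1L):(pad + delay + n)]
}

#' Apply the fixed filter chain to an epoch
#'
#' In order: 50 Hz notch (2nd-order IIR, Q = 35, zero-phase), 4th-order
#' Butterworth band-stop 60-100 Hz (zero-phase), then a linear-phase FIR
#' band-pass at the requested band edges.
#'
#' @param ep an `eeg_epoch`.
#' @param band band name or single-row band definition (see [eeg_bands()]).
#' @return Filtered epoch, same shape, with `band` set.
#' @export
apply_filter_chain <- function(ep, band = "full") {
  band <- band_row(band)
  fs <- ep$fs
  if (band$hi >= fs / 2)
    stop(sprintf("band upper edge %g Hz >= Nyquist %g Hz", band$hi, fs / 2))
  notch <- notch_biquad(50, fs)
  bstop <- signal::butter(4, c(60, 100) / (fs / 2), type = "stop")
  h <- design_fir_bandpass(band$lo, band$hi, fs)
  pad <- min(as.integer(2 * fs), ncol(ep$data) - 1L)
  dat <- t(apply(ep$data, 1L, function(x) {
    x <- zp_filter(notch, x, pad)
    x <- zp_filter(bstop, x, pad)
    fir_apply(h, x)
  }))
  out <- ep
  out$data <- dat
  out$band <- band$name
  out
}

#' Per-channel power ratio of cleaned vs raw epochs
#'
#' Mean-square power of the cleaned signal divided by that of the raw signal,
#' per channel. Ratios near 1 mean the cleaner changed little; ratios below 1
#' mean power (typically artifact power) was removed.
#'
#' @param clean,raw epochs of identical shape.
#' @return Named numeric vector of per-channel ratios; channels whose raw
#'   power is zero yield `NaN` with a warning.
#' @export
power_ratio <- function(clean, raw) {
  stopifnot(all(dim(clean$data) == dim(raw$data)))
  pc <- rowMeans(clean$data^2)
  pr <- rowMeans(raw$data^2)
  if (any(pr == 0)) warning("zero-power raw channel: ratio undefined")
  r <- pc / pr
  names(r) <- rownames(raw$data)
  r
}
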