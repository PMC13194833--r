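# MVAR fitting, the transfer matrix, and the three estimators.

test_that("BIC order selection recovers a known MVAR(2) and prefers p_min on noise", {
  A <- array(0, c(2, 2, 2))
  A[1, 1, 1] <- 0.5; A[2, 2, 1] <- 0.4; A[2, 1, 1] <- 0.3
  A[1, 1, 2] <- -0.3; A[2, 2, 2] <- -0.2
  sp <- ground_truth_spec(A, seed = 1)
  hits <- vapply(1:30, function(s) {
    rec <- generate_mvar_recording(sp, 6, 500, seed = s)
    fit_mvar(make_epoch(rec$data, 500), 1, 8)$order == 2L
  }, TRUE)
  expect_gte(mean(hits), 0.9)

  set.seed(2)
  wn <- make_epoch(matrix(rnorm(2 * 2000), 2), 500)
  expect_identical(fit_mvar(wn, 1, 8)$order, 1L)
})

test_that("fit_mvar validates sample size and reports instability", {
  expect_error(fit_mvar(make_epoch(matrix(rnorm(40), 2), 500), 1, 30),
               "too few samples")
})

test_that("transfer matrix matches closed forms", {
  # zero coefficients: identity at every bin
  m0 <- structure(list(order = 1L, coeffs = array(0, c(2, 2, 1)),
                       stable = TRUE, fs = 500), class = "mvar_model")
  H0 <- transfer_matrix(m0, freqs = c(1, 10, 40))
  for (b in 1:3) expect_equal(H0$H[, , b], diag(2) + 0i)

  # scalar AR(1), a = 0.5: |H(0)| = 2
  m1 <- structure(list(order = 1L, coeffs = array(0.5, c(1, 1, 1)),
                       stable = TRUE, fs = 500), class = "mvar_model")
  H1 <- transfer_matrix(m1, freqs = 0)
  expect_equal(Mod(H1$H[1, 1, 1]), 2)

  # known 2x2 coefficients vs brute-force polynomial inversion bin by bin
  A <- array(c(0.4, 0.3, 0, 0.5, -0.2, 0.1, 0.2, -0.3), c(2, 2, 2))
  m2 <- structure(list(order = 2L, coeffs = A, stable = TRUE, fs = 200),
                  class = "mvar_model")
  freqs <- seq(1, 90, by = 7)
  H2 <- transfer_matrix(m2, freqs = freqs)
  for (b in seq_along(freqs)) {
    z1 <- exp(-2i * pi * freqs[b] * 1 / 200)
    z2 <- exp(-2i * pi * freqs[b] * 2 / 200)
    Af <- diag(2) - A[, , 1] * z1 - A[, , 2] * z2
    # 2x2 inverse by the adjugate formula
    det <- Af[1, 1] * Af[2, 2] - Af[1, 2] * Af[2, 1]
    Hb <- matrix(c(Af[2, 2], -Af[2, 1], -Af[1, 2], Af[1, 1]), 2) / det
    expect_equal(H2$H[, , b], Hb, tolerance = 1e-12)
  }
})

test_that("DTF normalization, identity case, and direction recovery", {
  m0 <- structure(list(order = 1L, coeffs = array(0, c(3, 3, 1)),
                       stable = TRUE, fs = 500), class = "mvar_model")
  d0 <- dtf(transfer_matrix(m0), "alpha")
  expect_equal(d0$W, diag(3))

  # random stable models: inflow normalization to 1e-10 per band
  set.seed(3)
  for (r in 1:5) {
    A <- array(rnorm(9 * 2, 0, 0.15), c(3, 3, 2))
    while (spectral_radius(A) >= 0.95) A <- 0.8 * A
    m <- structure(list(order = 2L, coeffs = A, stable = TRUE, fs = 500),
                   class = "mvar_model")
    for (b in c("delta", "alpha", "gamma", "full")) {
      W <- dtf(transfer_matrix(m), b)$W
      expect_lt(max(abs(rowSums(W) - 1)), 1e-10)
    }
  }

  # analytic H of a unidirectional model: true direction dominates
  A <- array(0, c(2, 2, 1)); A[1, 1, 1] <- 0.3; A[2, 2, 1] <- 0.3
  A[2, 1, 1] <- 0.4
  m <- structure(list(order = 1L, coeffs = A, stable = TRUE, fs = 500),
                 class = "mvar_model")
  H <- transfer_matrix(m)
  for (b in c("delta", "theta", "alpha", "beta", "gamma", "full")) {
    W <- dtf(H, b)$W
    expect_gt(W[2, 1], W[1, 2])     # 1 -> 2 beats 2 -> 1
    expect_lt(W[1, 2], 0.05)
  }
})

test_that("cross-spectrum: self-coherence, independence bias, Parseval", {
  set.seed(4)
  x <- rnorm(3000)
  ep <- make_epoch(rbind(x, x), 500)
  S <- cross_spectrum(ep)
  co <- coherence(S, "full")
  expect_equal(max(co$W[1, 2], na.rm = TRUE), 1, tolerance = 1e-6)

  # independent channels: mean |COH|^2 ~ 1/n_segments bias
  long <- make_epoch(matrix(rnorm(2 * 60000), 2), 500)
  Sl <- cross_spectrum(long)
  expect_lt(mean(coherence(Sl, "full")$W[1, 2]), 3 / sqrt(Sl$n_segments))

  ps <- sum(Re(S$S[1, 1, ])) * diff(S$freqs[1:2])
  expect_equal(ps, var(x), tolerance = 0.02 * var(x))
  expect_error(cross_spectrum(make_epoch(matrix(rnorm(200), 2), 500),
                              seg_s = 1), "2 Welch segments")
})

test_that("iCOH is zero at 0 and pi phase and near 1 at quarter-period lag", {
  fs <- 500
  t <- (1:6000) / fs
  set.seed(5)
  base <- sin(2 * pi * 10 * t)
  tiny <- function() 0.01 * rnorm(length(t))
  # zero lag and antiphase: real coherency, Im = 0 at the driven bin
  im_at <- function(S, f) {
    b <- which(S$freqs == f)
    abs(Im(S$S[1, 2, b] / sqrt(Re(S$S[1, 1, b]) * Re(S$S[2, 2, b]))))
  }
  S0 <- cross_spectrum(make_epoch(rbind(base + tiny(), base + tiny()), fs))
  expect_lt(im_at(S0, 10), 0.05)
  Spi <- cross_spectrum(make_epoch(rbind(base + tiny(), -base + tiny()), fs))
  expect_lt(im_at(Spi, 10), 0.05)
  # quarter-period delay: phase pi/2 at 10 Hz
  Sq <- cross_spectrum(make_epoch(rbind(base + tiny(),
                                        sin(2 * pi * 10 * t - pi / 2) + tiny()),
                                  fs))
  bin10 <- which(Sq$freqs == 10)
  ic <- abs(Im(Sq$S[1, 2, bin10] /
                 sqrt(Re(Sq$S[1, 1, bin10]) * Re(Sq$S[2, 2, bin10]))))
  expect_gt(ic, 0.9)
})

test_that("wPLI hits its boundary cases", {
  fs <- 500
  t <- (1:6000) / fs
  set.seed(6)
  # zero-lag mixture of common sources: Im(S) ~ 0 at the driven bins
  s <- sin(2 * pi * 10 * t) + 0.3 * rnorm(length(t))
  ep0 <- make_epoch(rbind(s, 0.8 * s), fs)
  expect_lt(wpli(cross_spectrum(ep0), "alpha")$W[1, 2], 0.3)
  # consistent lag: all segments share the sign of Im(S)
  lagged <- make_epoch(rbind(sin(2 * pi * 10 * t) + 0.05 * rnorm(length(t)),
                             sin(2 * pi * 10 * t - pi / 2) + 0.05 * rnorm(length(t))),
                       fs)
  Sq <- cross_spectrum(lagged)
  bin10 <- which(Sq$freqs == 10)
  I <- Im(Sq$S_seg[1, 2, bin10, ])
  expect_true(all(sign(I) == sign(I[1])))
  expect_equal(abs(mean(I)) / mean(abs(I)), 1, tolerance = 1e-12)
  # sign-split imaginary parts: ratio tends to 0 with many segments
  nseg <- 2000
  Ihalf <- c(rnorm(nseg))
  expect_lt(abs(mean(Ihalf)) / mean(abs(Ihalf)), 0.05)
})

test_that("estimators are equivariant under channel relabeling", {
  set.seed(7)
  sp <- template_coupling(n_channels = 4, seed = 7)
  rec <- generate_mvar_recording(sp, 12, 500)
  ep <- make_epoch(rec$data, 500)
  perm <- c(3, 1, 4, 2)
  epp <- make_epoch(rec$data[perm, ], 500)

  m <- fit_mvar(ep, 1, 4); mp <- fit_mvar(epp, 1, 4)
  W <- dtf(transfer_matrix(m), "alpha")$W
  Wp <- dtf(transfer_matrix(mp), "alpha")$W
  expect_equal(Wp, W[perm, perm], tolerance = 1e-6)

  S <- cross_spectrum(ep); Sp <- cross_spectrum(epp)
  expect_equal(icoh(Sp, "alpha")$W, icoh(S, "alpha")$W[perm, perm],
               tolerance = 1e-10)
  expect_equal(wpli(Sp, "alpha")$W, wpli(S, "alpha")$W[perm, perm],
               tolerance = 1e-10)
})

test_that("estimated band DTF tracks the analytic DTF of the generating model", {
  sp <- template_coupling(n_channels = 6, seed = 8)
  rec <- generate_mvar_recording(sp, 120, 500)
  m <- fit_mvar(make_epoch(rec$data, 500), 1, 6)
  freqs <- seq(0.5, 60, by = 0.5)
  Hhat <- transfer_matrix(m, freqs = freqs)
  Htrue <- structure(list(H = analytic_transfer(sp, freqs, 500), freqs = freqs),
                     class = "transfer_matrix")
  west <- as.numeric(dtf(Hhat, "full")$W)
  wtrue <- as.numeric(dtf(Htrue, "full")$W)
  expect_gt(cor(west, wtrue), 0.95)
})
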