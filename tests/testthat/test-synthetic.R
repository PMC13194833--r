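# Ground-truth simulation: stationarity, directionality, determinism,
# artifact injection, cohort assembly, EDF round trip.

test_that("zero-coupling white noise has vanishing cross-correlation", {
  sp <- ground_truth_spec(array(0, c(3, 3, 1)), seed = 1)
  rec <- generate_mvar_recording(sp, 60, 250)
  cc <- cor(t(rec$data))
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.05)
})

test_that("unidirectional lag-1 coupling shows up in the lagged cross-correlation", {
  A <- array(0, c(2, 2, 1)); A[2, 1, 1] <- 0.4
  sp <- ground_truth_spec(A, seed = 2)
  rec <- generate_mvar_recording(sp, 120, 250)
  x <- rec$data[1, ]; y <- rec$data[2, ]
  n <- length(x)
  fwd <- cor(x[-n], y[-1])   # x1[t] vs x2[t+1]
  bwd <- cor(y[-n], x[-1])
  expect_gt(fwd, bwd)
  # closed-form stationary cross-covariance of the generating MVAR(1)
  th <- oracle_mvar1_autocov(A[, , 1], diag(2))
  rho_fwd <- th$G1[2, 1] / sqrt(th$G0[1, 1] * th$G0[2, 2])
  expect_equal(fwd, rho_fwd, tolerance = 0.05)
  expect_equal(rho_fwd, 0.4 / sqrt(1.16), tolerance = 1e-6)
})

test_that("same seed and spec give identical samples; unstable spec is rejected", {
  A <- array(0.3, c(2, 2, 1))
  sp <- ground_truth_spec(A, seed = 3)
  r1 <- generate_mvar_recording(sp, 4, 100)
  r2 <- generate_mvar_recording(sp, 4, 100)
  expect_identical(r1$data, r2$data)
  bad <- array(0, c(2, 2, 1)); bad[1, 1, 1] <- 1.05
  expect_error(ground_truth_spec(bad), "spectral radius 1.05")
})

test_that("artifact injection: identity at zero rates, sinusoid power, Poisson counts", {
  sp <- template_coupling(n_channels = 4, seed = 4)
  rec <- generate_mvar_recording(sp, 20, 500)

  sp0 <- ground_truth_spec(sp$coupling, artifact_spec = list(), seed = 4)
  expect_identical(inject_artifacts(rec, sp0)$data, rec$data)

  amp <- 8
  spl <- ground_truth_spec(sp$coupling,
                           artifact_spec = list(line = list(amplitude = amp)),
                           seed = 4)
  ri <- inject_artifacts(rec, spl)
  p50 <- function(x) {
    n <- length(x)
    2 * Mod(fft(x))[round(50 * n / 500) + 1]^2 / n^2
  }
  gain <- p50(ri$data[1, ]) - p50(rec$data[1, ])
  expect_equal(gain, amp^2 / 2, tolerance = 0.05 * amp^2)

  # Poisson counts: rate 0.1/s over 240 s, total over 200 seeds
  spe <- ground_truth_spec(sp$coupling,
                           artifact_spec = list(emg = list(rate = 0.1, amplitude = 5)),
                           seed = 4)
  short <- generate_mvar_recording(sp, 240, 100, seed = 5)
  counts <- vapply(1:200, function(s) {
    length(attr(inject_artifacts(short, spe, seed = s), "artifact_log")$emg)
  }, 0)
  total <- sum(counts)   # Poisson(200 * 24)
  lam <- 200 * 24
  expect_gt(total, qpois(0.005, lam))
  expect_lt(total, qpois(0.995, lam))
})

test_that("cohort has the right size, group effect and psychometric coupling", {
  base <- template_coupling(seed = 6)
  base$group_effect <- list(type = "edge_removal", fraction = 0.2)
  co <- generate_cohort(base, n_per_group = 19, states = c("EO", "EC"),
                        duration_s = 4, fs = 100, seed = 6)
  expect_length(co$recordings, 76)   # 19 x 2 groups x 2 states
  expect_equal(nrow(co$manifest), 76)

  cc <- co$psychometrics$true_clustering
  grp <- co$psychometrics$group
  # forced by construction: removing edges lowers true clustering
  expect_lt(mean(cc[grp == "Miners"]), mean(cc[grp == "Control"]))
  # recall was generated with negative dependence on true clustering
  expect_lt(cor(co$psychometrics$recall, cc), 0)
  # all per-subject specs stable
  expect_true(all(vapply(co$subject_specs, function(s) s$spectral_radius < 1,
                         TRUE)))
})

test_that("degenerate group effect removing all edges errors", {
  base <- template_coupling(n_channels = 4, seed = 7)
  base$group_effect <- list(type = "edge_removal", fraction = 1)
  expect_error(generate_cohort(base, n_per_group = 2, states = "EO",
                               duration_s = 2, fs = 100, seed = 7),
               "remove all")
})

test_that("EDF round trip preserves signals within quantization and metadata", {
  sp <- template_coupling(n_channels = 4, seed = 8)
  rec <- generate_mvar_recording(sp, 5, 100, subject_id = "M03",
                                 group = "Miners", state = "EC")
  f <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, f)
  back <- read_edf(f)
  qstep <- (apply(rec$data, 1, max) - apply(rec$data, 1, min)) / 65535
  expect_true(all(abs(back$data - rec$data) <= 1.01 * qstep + 1e-12))
  expect_identical(back$channel_labels, rec$channel_labels)
  expect_identical(back$subject_id, "M03")
  expect_identical(back$group, "Miners")
  expect_identical(back$state, "EC")
})
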