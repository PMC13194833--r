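# ICC(3,k), the reliability bins, the mixed model, effect size, FDR,
# correlations, and the summary-statistic t-test.

test_that("ICC(3,k) worked examples and invariances", {
  # duplicated identical rows: EMS = 0, ICC exactly 1
  M <- rbind(c(1, 2, 3), c(1, 2, 3))
  expect_identical(icc_3k(M), 1)
  M40 <- matrix(rep(c(2, 5, 9, 4), each = 40), nrow = 40)
  expect_identical(icc_3k(M40), 1)

  # hand ANOVA on a 2-rater x 3-target grid
  Mh <- rbind(c(1, 2, 4), c(2, 4, 5))
  k <- 2; n <- 3
  grand <- mean(Mh)
  bms <- k * sum((colMeans(Mh) - grand)^2) / (n - 1)
  rms <- n * sum((rowMeans(Mh) - grand)^2) / (k - 1)
  ems <- (sum((Mh - grand)^2) - (n - 1) * bms - (k - 1) * rms) /
    ((n - 1) * (k - 1))
  expect_equal(icc_3k(Mh), (bms - ems) / bms, tolerance = 1e-10)

  # affine invariance
  expect_equal(icc_3k(3 * Mh + 7), icc_3k(Mh), tolerance = 1e-12)

  # reversed-rater grid has zero between-target variance: undefined
  und <- icc_3k(rbind(c(1, 2, 3), c(3, 2, 1)))
  expect_true(is.na(und))
  expect_match(attr(und, "undefined"), "between-target")
})

test_that("null ICC distribution centers near zero for many targets", {
  set.seed(1)
  vals <- replicate(300, icc_3k(matrix(rnorm(20 * 100), 20, 100)))
  expect_lt(abs(mean(vals)), 0.05)
})

test_that("ICC labels follow the published bins; negatives are flagged poor", {
  expect_identical(as.character(classify_icc(0.75)), "excellent")
  expect_identical(as.character(classify_icc(0.60)), "good")
  expect_identical(as.character(classify_icc(0.74)), "good")
  expect_identical(as.character(classify_icc(0.40)), "fair")
  expect_identical(as.character(classify_icc(0.39)), "poor")
  neg <- classify_icc(-0.2)
  expect_identical(as.character(neg), "poor")
  expect_true(attr(neg, "negative"))
  expect_true(is.na(classify_icc(NA_real_)))
})

test_that("exchangeable subjects reduce the LME to the raw group mean difference", {
  set.seed(2)
  grp <- rep(c("Control", "Miners"), each = 6 * 10)
  subj <- rep(1:12, each = 10)
  val <- 2 + 0.4 * (grp == "Miners") + rnorm(120, 0, 0.3)   # sigma_u = 0
  r <- fit_group_lme(data.frame(Value = val, Group = grp, Subject = subj))
  raw_diff <- mean(val[grp == "Miners"]) - mean(val[grp == "Control"])
  expect_equal(r$beta1, raw_diff, tolerance = 1e-7)
  expect_true(r$ci[1] <= r$beta1 && r$beta1 <= r$ci[2])
  expect_gte(r$sigma_u2, 0)
})

test_that("balanced designs give beta1 equal to the difference of subject-mean group means", {
  set.seed(3)
  grp <- rep(c("Control", "Miners"), each = 8 * 15)
  subj <- rep(1:16, each = 15)
  val <- 1 - 0.25 * (grp == "Miners") + rep(rnorm(16, 0, 0.4), each = 15) +
    rnorm(240, 0, 0.6)
  r <- fit_group_lme(data.frame(Value = val, Group = grp, Subject = subj))
  sm <- tapply(val, subj, mean)
  gm <- tapply(sm, tapply(grp, subj, unique), mean)
  expect_equal(r$beta1, unname(gm["Miners"] - gm["Control"]), tolerance = 1e-8)
})

test_that("Cohen's f2 closed forms and monotonicity", {
  set.seed(4)
  # beta1 = 0 implies f2 = 0
  r0 <- list(beta1 = 0, sigma_u2 = 1, sigma2 = 1)
  t0 <- data.frame(Group = rep(c("Control", "Miners"), each = 10))
  expect_equal(cohens_f2(r0, t0), 0)
  # constructed: fixed-effect variance = 0.13 of total -> f2 = 0.13/0.87
  # balanced groups: var_fixed = beta1^2 / 4
  beta1 <- 2
  varf <- beta1^2 / 4
  tot_rest <- varf / 0.13 - varf
  rc <- list(beta1 = beta1, sigma_u2 = tot_rest / 2, sigma2 = tot_rest / 2)
  expect_equal(cohens_f2(rc, t0), 0.13 / 0.87, tolerance = 1e-10)
  # monotone in |beta1| with variances held fixed
  f2s <- vapply(seq(0, 2, by = 0.25), function(b)
    cohens_f2(list(beta1 = b, sigma_u2 = 0.5, sigma2 = 0.5), t0), 0)
  expect_true(all(diff(f2s) > 0))
})

test_that("BH adjustment matches the hand step-up rule", {
  expect_equal(fdr_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_bh(0.37), 0.37)
  set.seed(5)
  for (r in 1:20) {
    p <- runif(sample(3:40, 1))
    adj <- fdr_bh(p)
    expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-12))
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
  }
})

test_that("psychometric correlations: exact case, recovery, null calibration", {
  x <- c(1, 3, 2, 5, 4, 6)
  im <- data.frame(subject_id = paste0("S", 1:6), CC = x)
  sc <- data.frame(subject_id = paste0("S", 1:6), recall = -x)
  res <- correlate_with_psychometrics(im, sc)
  expect_equal(res$r, -1, tolerance = 1e-12)
  expect_lt(res$p_fdr, 1e-6)

  # power at the generator's effect size: |r_true| = 0.6, n = 19
  set.seed(6)
  hits <- replicate(60, {
    z <- rnorm(19)
    y <- -0.6 * z + sqrt(1 - 0.36) * rnorm(19)
    im <- data.frame(subject_id = 1:19, CC = z)
    sc <- data.frame(subject_id = 1:19, recall = y)
    r <- correlate_with_psychometrics(im, sc)
    r$r < 0 && r$p_fdr <= 0.05
  })
  expect_gte(mean(hits), 0.7)

  # null: FDR-significant rate stays near the nominal level
  set.seed(7)
  false_pos <- replicate(200, {
    im <- data.frame(subject_id = 1:19, CC = rnorm(19))
    sc <- data.frame(subject_id = 1:19, recall = rnorm(19))
    correlate_with_psychometrics(im, sc)$significant
  })
  expect_lte(mean(false_pos), 0.08)

  # degenerate pair flagged
  im0 <- data.frame(subject_id = 1:5, CC = rep(1, 5))
  sc0 <- data.frame(subject_id = 1:5, recall = rnorm(5))
  r0 <- correlate_with_psychometrics(im0, sc0)
  expect_true(is.na(r0$r))
  expect_match(r0$note, "degenerate")
})

test_that("summary-statistic t-test reproduces hand arithmetic", {
  # equal summaries: t = 0, p = 1
  r <- t_from_summary(12.63, 2.00, 19, 12.63, 2.00, 19)
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
  expect_equal(r$df, 36)
  # hand pooled-variance case: t = sqrt(2)
  r2 <- t_from_summary(10, 2, 4, 8, 2, 4)
  expect_equal(r2$t, sqrt(2), tolerance = 1e-12)
  expect_equal(r2$p, 2 * pt(-sqrt(2), 6), tolerance = 1e-12)
  # degenerate zero-SD equal means
  r3 <- t_from_summary(5, 0, 3, 5, 0, 3)
  expect_equal(r3$t, 0)
  expect_equal(r3$p, 1)
})
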