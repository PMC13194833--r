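# ICC(3,k) reliability screening and the group-inference statistics: a
# random-intercept linear mixed model per index, BH-FDR over the whole test
# family, Cohen's f2 from the marginal R2, Pearson correlations against
# psychometric scores, and pooled-variance t from printed summaries.

#' ICC(3,k): two-way mixed, consistency, average measures
#'
#' `M` is a raters x targets grid; in the reliability screening, rows are
#' the repeated epochs (k = 40) and columns the subjects. From the two-way
#' ANOVA mean squares (between-targets BMS, residual EMS):
#' `ICC(3,k) = (BMS - EMS) / BMS`.
#'
#' @param M numeric matrix, raters (epochs) x targets (subjects).
#' @return The ICC value; `NA` with an `"undefined"` attribute when the
#'   between-target variance is zero. Negative values are returned as
#'   computed, not truncated.
#' @export
icc_3k <- function(M) {
  M <- as.matrix(M)
  k <- nrow(M); n <- ncol(M)
  if (k < 2L || n < 2L) stop("need >= 2 raters and >= 2 targets")
  grand <- mean(M)
  col_m <- colMeans(M)
  row_m <- rowMeans(M)
  ss_col <- k * sum((col_m - grand)^2)
  ss_row <- n * sum((row_m - grand)^2)
  ss_tot <- sum((M - grand)^2)
  ss_err <- ss_tot - ss_col - ss_row
  bms <- ss_col / (n - 1L)
  ems <- ss_err / ((n - 1L) * (k - 1L))
  if (bms <= .Machine$double.eps * abs(grand + 1)) {
    out <- NA_real_
    attr(out, "undefined") <- "zero between-target variance"
    return(out)
  }
  (bms - ems) / bms
}

#' Classify an ICC value into reliability bins
#'
#' poor < 0.40 <= fair < 0.60 <= good < 0.75 <= excellent. Negative values
#' are labeled poor and flagged via the `"negative"` attribute; values of
#' 0.60 and above count as acceptable for the screening rule.
#'
#' @param icc ICC value (may be `NA`).
#' @return Factor level among `poor`, `fair`, `good`, `excellent` (as a
#'   character), or `NA` for undefined input.
#' @export
classify_icc <- function(icc) {
  if (is.na(icc)) return(NA_character_)
  lab <- if (icc < 0.40) "poor" else if (icc < 0.60) "fair" else
    if (icc < 0.75) "good" else "excellent"
  if (icc < 0) attr(lab, "negative") <- TRUE
  lab
}

#' Fit the group-difference random-intercept model
#'
#' `Value ~ Group + (1 | Subject)` by REML. The `Group` factor is releveled
#' so the stated reference group is first; the fixed effect `beta1` is the
#' exposed-minus-reference mean difference with a Wald 95% CI. The p-value
#' for `beta1` is a Wald z test by default, or Satterthwaite if requested
#' (requires the `lmerTest` package).
#'
#' @param t data.frame with columns `Value`, `Group`, `Subject` (and
#'   optionally `Epoch`).
#' @param reference reference level of `Group` (default `"Control"`).
#' @param df_method `"wald"` (default) or `"satterthwaite"`.
#' @return Object of class `lme_result`: `beta0`, `beta1`, `ci` (95% for
#'   beta1), `p_value`, `sigma_u2`, `sigma2`, `f2`, `singular`, plus the
#'   fitted `lme4` model in `$fit`.
#' @export
fit_group_lme <- function(t, reference = "Control",
                          df_method = c("wald", "satterthwaite")) {
  df_method <- match.arg(df_method)
  stopifnot(all(c("Value", "Group", "Subject") %in% names(t)))
  t$Group <- stats::relevel(factor(t$Group), ref = reference)
  t$Subject <- factor(t$Subject)
  if (any(table(unique(t[c("Subject", "Group")])$Group) < 2L))
    stop("need at least 2 subjects per group")
  fit <- lme4::lmer(Value ~ Group + (1 | Subject), data = t, REML = TRUE)
  fe <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  beta1 <- unname(fe[2L]); se1 <- se[2L]
  if (df_method == "satterthwaite") {
    if (!requireNamespace("lmerTest", quietly = TRUE))
      stop("Satterthwaite p-values need the lmerTest package")
    fitT <- lmerTest::lmer(Value ~ Group + (1 | Subject), data = t, REML = TRUE)
    p <- stats::coef(summary(fitT))[2L, "Pr(>|t|)"]
  } else {
    p <- 2 * stats::pnorm(-abs(beta1 / se1))
  }
  vc <- as.data.frame(lme4::VarCorr(fit))
  sigma_u2 <- vc$vcov[vc$grp == "Subject"]
  sigma2 <- vc$vcov[vc$grp == "Residual"]
  res <- structure(
    list(beta0 = unname(fe[1L]), beta1 = beta1,
         ci = c(beta1 - 1.96 * se1, beta1 + 1.96 * se1),
         se = unname(se1), p_value = unname(p),
         sigma_u2 = sigma_u2, sigma2 = sigma2,
         singular = lme4::isSingular(fit), fit = fit),
    class = "lme_result")
  res$f2 <- cohens_f2(res, t)
  res
}

#' @export
print.lme_result <- function(x, ...) {
  cat(sprintf("<lme_result> beta1 = %.4g [%.4g, %.4g], p = %.3g, f2 = %.3g\n",
              x$beta1, x$ci[1L], x$ci[2L], x$p_value, x$f2))
  cat(sprintf("  sigma_u2 = %.4g, sigma2 = %.4g%s\n", x$sigma_u2, x$sigma2,
              if (x$singular) " (singular fit)" else ""))
  invisible(x)
}

#' Cohen's f2 for the group fixed effect
#'
#' `f2 = R2m / (1 - R2m)` where the marginal R2 is the fixed-effect
#' variance over the total variance (fixed + random intercept + residual).
#' Benchmarks: 0.02 small, 0.15 medium, 0.35 large.
#'
#' @param r an `lme_result` (or anything with `beta1`, `sigma_u2`,
#'   `sigma2`).
#' @param t the long table the model was fitted to.
#' @return Cohen's f2 (non-negative).
#' @export
cohens_f2 <- function(r, t) {
  g <- factor(t$Group)
  x <- as.numeric(g == levels(g)[2L])
  var_fixed <- r$beta1^2 * stats::var(x) * (length(x) - 1L) / length(x)
  r2m <- var_fixed / (var_fixed + r$sigma_u2 + r$sigma2)
  r2m / (1 - r2m)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (monotone in rank, capped at 1), the family
#' being all tests passed in together.
#'
#' @param p vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as input.
#' @export
fdr_bh <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Pearson correlations of subject-level index means with psychometrics
#'
#' Averages the per-epoch index over epochs within each subject, correlates
#' the result with each psychometric column (Pearson, two-tailed), and
#' BH-adjusts across all tested pairs as one family.
#'
#' @param index_means data.frame with `subject_id` plus one column per
#'   index (already epoch-averaged), or a named list of per-subject vectors.
#' @param scores data.frame with `subject_id` plus psychometric columns.
#' @param alpha significance level on the adjusted p-values (default 0.05).
#' @return data.frame with `index`, `score`, `n`, `r`, `p`, `p_fdr`,
#'   `significant`; pairs with zero variance are returned with `NA` and
#'   flagged in `note`.
#' @export
correlate_with_psychometrics <- function(index_means, scores, alpha = 0.05) {
  stopifnot("subject_id" %in% names(index_means),
            "subject_id" %in% names(scores))
  common <- intersect(index_means$subject_id, scores$subject_id)
  if (length(common) < 4L) stop("need at least 4 complete subjects")
  im <- index_means[match(common, index_means$subject_id), , drop = FALSE]
  sc <- scores[match(common, scores$subject_id), , drop = FALSE]
  idx_cols <- setdiff(names(im), "subject_id")
  sc_cols <- setdiff(names(sc),
                     c("subject_id", "group", "true_clustering"))
  out <- NULL
  for (ic in idx_cols) for (scn in sc_cols) {
    x <- im[[ic]]; y <- sc[[scn]]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 4L || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      out <- rbind(out, data.frame(index = ic, score = scn, n = sum(ok),
                                   r = NA_real_, p = NA_real_,
                                   note = "degenerate pair"))
    } else {
      ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
      out <- rbind(out, data.frame(index = ic, score = scn, n = sum(ok),
                                   r = unname(ct$estimate),
                                   p = ct$p.value, note = ""))
    }
  }
  out$p_fdr <- NA_real_
  ok <- !is.na(out$p)
  out$p_fdr[ok] <- fdr_bh(out$p[ok])
  out$significant <- !is.na(out$p_fdr) & out$p_fdr <= alpha
  out
}

#' Pooled-variance two-sample t-test from printed summaries
#'
#' Reconstructs the independent-samples t statistic and two-tailed p-value
#' from group means, SDs and sizes (df = n1 + n2 - 2), as used for
#' demographic tables. Two zero-SD groups with equal means give t = 0,
#' p = 1 by convention.
#'
#' @param m1,sd1,n1 mean, SD and size of group 1.
#' @param m2,sd2,n2 mean, SD and size of group 2.
#' @return List with `t`, `df`, `p`.
#' @export
t_from_summary <- function(m1, sd1, n1, m2, sd2, n2) {
  stopifnot(n1 >= 2L, n2 >= 2L, sd1 >= 0, sd2 >= 0)
  df <- n1 + n2 - 2L
  sp2 <- ((n1 - 1L) * sd1^2 + (n2 - 1L) * sd2^2) / df
  if (sp2 == 0) {
    tval <- if (m1 == m2) 0 else Inf * sign(m1 - m2)
  } else {
    tval <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  }
  p <- if (is.finite(tval)) 2 * stats::pt(-abs(tval), df) else 0
  list(t = tval, df = df, p = p)
}
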