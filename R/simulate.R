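# Synthetic cohort generation: realizations of the ground-truth MVAR process,
# scripted artifacts, and full two-group cohorts with per-subject jitter and a
# controlled topology shift in the exposed group.

chol_lower <- function(S) t(chol(S))

# sample k elements from an index vector (safe for length-1 vectors, where
# base sample() would draw from 1:x)
sample_idx <- function(x, k) x[sample.int(length(x), k)]

#' Simulate a recording from a ground-truth MVAR specification
#'
#' Draws a realization of the stable MVAR(p) source process with Gaussian
#' innovations, applies the zero-lag mixing matrix (volume-conduction
#' surrogate), and wraps the result as a recording. A 2-second burn-in is
#' generated and discarded so the returned samples are from the stationary
#' distribution. Deterministic given `seed`.
#'
#' @param spec a [ground_truth_spec()].
#' @param duration_s recording length in seconds.
#' @param fs sampling rate in Hz (default 500).
#' @param seed integer seed; defaults to `spec$seed`.
#' @param scale_uv output scale in microvolts per unit source amplitude
#'   (default 10, giving realistic EEG amplitudes).
#' @param subject_id,group,state metadata carried into the recording.
#' @return An [eeg_recording()].
#' @export
generate_mvar_recording <- function(spec, duration_s, fs = 500,
                                    seed = spec$seed, scale_uv = 10,
                                    subject_id = "S01", group = "Control",
                                    state = "EO") {
  stopifnot(inherits(spec, "ground_truth_spec"))
  nsamp <- duration_s * fs
  if (abs(nsamp - round(nsamp)) > 1e-9)
    stop("duration_s * fs must be an integer number of samples")
  nsamp <- as.integer(round(nsamp))
  n <- spec$n_channels; p <- spec$mvar_order
  burn <- as.integer(2 * fs)

  set.seed(seed)
  L <- chol_lower(spec$noise_cov)
  innov <- L %*% matrix(stats::rnorm(n * (nsamp + burn)), n)
  x <- matrix(0, n, nsamp + burn + p)    # p zero columns of pre-history
  Abig <- matrix(spec$coupling, n, n * p)  # [A_1 A_2 ... A_p]
  for (t in seq_len(nsamp + burn)) {
    tc <- t + p
    xlag <- x[, tc - seq_len(p), drop = FALSE]
    x[, tc] <- innov[, t] + Abig %*% as.vector(xlag)
  }
  x <- x[, (p + 1L):(p + nsamp + burn), drop = FALSE]
  y <- spec$mixing %*% x[, (burn + 1L):(burn + nsamp), drop = FALSE]
  labels <- if (n == 20L) montage_1020() else paste0("ch", seq_len(n))
  eeg_recording(scale_uv * y, fs, labels, subject_id = subject_id,
                group = group, state = state)
}

blink_kernel <- function(fs, width_s = 0.4) {
  # raised-cosine-squared bump: low-frequency, strictly positive transient
  t <- seq(0, width_s, by = 1 / fs)
  (0.5 - 0.5 * cos(2 * pi * t / width_s))^2
}

frontal_weights <- function(labels) {
  w <- rep(0.1, length(labels))
  w[grepl("^Fp", labels)] <- 1
  w[grepl("^F[0-9z]", labels)] <- 0.5
  w
}

#' Inject scripted artifacts into a recording
#'
#' Adds, at the configured rates and amplitudes: (a) a 50 Hz line-noise
#' sinusoid on every channel; (b) frontally weighted blink transients
#' (0.4-s raised-cosine-squared bumps) at Poisson onsets; (c) broadband
#' 60-100 Hz EMG bursts (0.3 s, Hann envelope) on random channel subsets at
#' Poisson onsets. With all rates/amplitudes absent or zero the recording is
#' returned unchanged. The injected event times are attached as the
#' `"artifact_log"` attribute.
#'
#' @param rec an [eeg_recording()].
#' @param spec a [ground_truth_spec()] whose `artifact_spec` drives injection.
#' @param seed integer seed (default `spec$seed + 1`).
#' @return An [eeg_recording()] with artifacts added and an `artifact_log`
#'   attribute listing onset times per artifact type.
#' @export
inject_artifacts <- function(rec, spec, seed = spec$seed + 1L) {
  as <- spec$artifact_spec
  if (!length(as)) return(rec)
  dat <- rec$data
  fs <- rec$fs
  nsamp <- ncol(dat)
  dur <- nsamp / fs
  log <- list(line = numeric(0), blink = numeric(0), emg = numeric(0))
  set.seed(seed)

  if (!is.null(as$line) && isTRUE(as$line$amplitude > 0)) {
    tt <- seq_len(nsamp) / fs
    phase <- stats::runif(1, 0, 2 * pi)
    wave <- as$line$amplitude * sin(2 * pi * 50 * tt + phase)
    dat <- sweep(dat, 2L, wave, `+`)
    log$line <- 0
  }
  if (!is.null(as$blink) && isTRUE(as$blink$rate > 0)) {
    k <- blink_kernel(fs)
    w <- frontal_weights(rec$channel_labels)
    n_ev <- stats::rpois(1, as$blink$rate * dur)
    onsets <- sort(stats::runif(n_ev, 0, dur - length(k) / fs))
    for (on in onsets) {
      i0 <- as.integer(round(on * fs)) + 1L
      idx <- i0:(i0 + length(k) - 1L)
      amp <- as$blink$amplitude * stats::runif(1, 0.7, 1.3)
      dat[, idx] <- dat[, idx] + amp * outer(w, k)
    }
    log$blink <- onsets
  }
  if (!is.null(as$emg) && isTRUE(as$emg$rate > 0)) {
    burst_s <- 0.3
    blen <- as.integer(burst_s * fs)
    env <- 0.5 - 0.5 * cos(2 * pi * seq_len(blen) / blen)
    hi <- min(100, 0.95 * fs / 2)       # clamp below Nyquist at low rates
    lo <- min(60, 0.6 * hi)
    bf <- signal::butter(4, c(lo, hi) / (fs / 2), type = "pass")
    n_ev <- stats::rpois(1, as$emg$rate * dur)
    onsets <- sort(stats::runif(n_ev, 0, dur - burst_s))
    nch <- nrow(dat)
    for (on in onsets) {
      i0 <- as.integer(round(on * fs)) + 1L
      idx <- i0:(i0 + blen - 1L)
      chs <- sample(nch, max(1L, stats::rbinom(1, nch, 0.3)))
      for (ch in chs) {
        noise <- signal::filtfilt(bf, stats::rnorm(blen + 2L * fs))
        noise <- noise[(fs + 1L):(fs + blen)]
        dat[ch, idx] <- dat[ch, idx] +
          as$emg$amplitude * env * noise / stats::sd(noise)
      }
    }
    log$emg <- onsets
  }
  out <- eeg_recording(dat, fs, rec$channel_labels, rec$subject_id,
                       rec$group, rec$state)
  attr(out, "artifact_log") <- log
  out
}

# stationary per-channel SDs of an MVAR(p) with unit innovations, via the
# companion-form Lyapunov fixed point (converges geometrically for sr < 1)
stationary_sd <- function(A, iters = 400L) {
  n <- dim(A)[1L]; p <- dim(A)[3L]
  FF <- matrix(0, n * p, n * p)
  for (k in seq_len(p)) FF[1:n, ((k - 1L) * n + 1L):(k * n)] <- A[, , k]
  if (p > 1L) FF[(n + 1L):(n * p), 1:(n * (p - 1L))] <- diag(n * (p - 1L))
  Q <- matrix(0, n * p, n * p); Q[1:n, 1:n] <- diag(n)
  P <- Q
  for (i in seq_len(iters)) P <- FF %*% P %*% t(FF) + Q
  sqrt(diag(P)[1:n])
}

# similarity transform equalizing stationary channel variances (preserves
# the coupling graph, eigenvalues and stability)
normalize_variance <- function(A) {
  s <- stationary_sd(A)
  D <- diag(1 / s); Di <- diag(s)
  for (k in seq_len(dim(A)[3L])) A[, , k] <- D %*% A[, , k] %*% Di
  A
}

# cells where cross-coupling is allowed: strictly lower-triangular within a
# bandwidth, giving a feed-forward (acyclic) flow whose stability is set by
# the oscillator poles alone
allowed_cells <- function(n, bandwidth = 6L) {
  which(row(diag(n)) > col(diag(n)) &
          row(diag(n)) - col(diag(n)) <= bandwidth)
}

#' Default 20-channel group-template coupling
#'
#' Builds the cohort template: each channel is a damped stochastic
#' oscillator (alpha-band resonance near 10 Hz), organized into four
#' 5-channel modules with denser directed coupling inside modules than
#' between them. Cross-channel influence is feed-forward (strictly
#' lower-triangular within a bandwidth), so the process is stable for any
#' coupling strength — its companion eigenvalues are exactly the oscillator
#' poles — and strong directed flow can be imposed without a stability
#' shrink. A similarity transform equalizes stationary channel variances.
#'
#' @param n_channels number of channels (default 20).
#' @param p MVAR order (default 3; lags 1-2 hold the oscillator poles,
#'   cross-coupling sits on lags 1-2).
#' @param within_density,between_density directed edge probabilities inside /
#'   across modules (among the allowed banded cells).
#' @param coupling_strength nominal magnitude of cross-channel coefficients
#'   before variance normalization (default 0.5).
#' @param bandwidth maximum source-to-sink index distance for coupling
#'   (default 5).
#' @param osc_r oscillator pole radius (default 0.8); also the companion
#'   spectral radius.
#' @param seed integer seed.
#' @return A [ground_truth_spec()] with identity noise and mixing, module
#'   labels attached.
#' @export
template_coupling <- function(n_channels = 20L, p = 3L,
                              within_density = 0.9, between_density = 0.35,
                              coupling_strength = 0.5, bandwidth = 6L,
                              osc_r = 0.8, seed = 1L) {
  set.seed(seed)
  n <- n_channels
  A <- array(0, c(n, n, p))
  w <- 2 * pi * 10 / 500
  for (i in seq_len(n)) {
    A[i, i, 1] <- 2 * osc_r * cos(w)
    A[i, i, 2] <- -osc_r^2
  }
  module <- rep(seq_len(ceiling(n / 5)), each = 5L)[seq_len(n)]
  for (cell in allowed_cells(n, bandwidth)) {
    i <- row(diag(n))[cell]; j <- col(diag(n))[cell]
    dens <- if (module[i] == module[j]) within_density else between_density
    if (stats::runif(1) < dens) {
      lag <- sample(1:2, 1)
      A[cell + (lag - 1L) * n * n] <- coupling_strength *
        sample(c(-1, 1), 1) * stats::runif(1, 0.7, 1.3)
    }
  }
  A <- normalize_variance(A)
  ground_truth_spec(A, modules = module, seed = seed)
}

#' Default zero-lag mixing matrix (volume-conduction surrogate)
#'
#' Unit-diagonal matrix whose off-diagonal weights decay with inter-channel
#' index distance, mimicking instantaneous field spread across the montage.
#'
#' @param n_channels channel count.
#' @param strength peak off-diagonal leak (default 0.25).
#' @param falloff decay rate per unit index distance.
#' @return `n x n` mixing matrix.
#' @export
default_mixing <- function(n_channels = 20L, strength = 0.25, falloff = 0.6) {
  d <- abs(outer(seq_len(n_channels), seq_len(n_channels), `-`))
  M <- strength * exp(-falloff * (d - 1))
  diag(M) <- 1
  M
}

true_edge_matrix <- function(spec) {
  E <- apply(spec$coupling != 0, c(1, 2), any)
  diag(E) <- FALSE
  E * 1
}

# the exposed group's topology shift, applied to a subject's coupling stack
apply_group_effect <- function(A, effect, modules) {
  if (is.null(effect)) return(A)
  n <- dim(A)[1L]; p <- dim(A)[3L]
  Eoff <- apply(A != 0, c(1, 2), any) & diag(n) == 0
  E <- which(Eoff)
  zero_cells <- function(cells) {
    for (k in seq_len(p)) {
      Ak <- A[, , k]; Ak[cells] <- 0
      A[, , k] <<- Ak
    }
  }
  if (effect$type == "edge_removal") {
    n_remove <- round(effect$fraction * length(E))
    if (n_remove >= length(E))
      stop("group effect would remove all coupling edges")
    zero_cells(sample_idx(E, n_remove))
  } else if (effect$type == "desegregation") {
    if (is.null(modules))
      stop("desegregation effect needs module labels on the template spec")
    same_mod <- outer(modules, modules, `==`)
    within <- E[same_mod[E]]
    free <- setdiff(allowed_cells(n)[!same_mod[allowed_cells(n)]],
                    which(Eoff))
    k_rw <- min(round(effect$fraction * length(within)), length(free))
    if (k_rw >= length(E))
      stop("group effect would remove all coupling edges")
    if (k_rw > 0) {
      strength <- stats::median(abs(A[A != 0 & rep(diag(n) == 0, p)]))
      zero_cells(sample_idx(within, k_rw))
      for (cell in sample_idx(free, k_rw)) {
        lag <- sample(seq_len(min(2L, p)), 1)
        A[cell + (lag - 1L) * n * n] <- strength * sample(c(-1, 1), 1) *
          stats::runif(1, 0.7, 1.3)
      }
    }
  } else stop("unknown group effect type: ", effect$type)
  A
}

subject_spec <- function(base, jitter_sd, effect, seed,
                         rewire_frac = 0.4) {
  set.seed(seed)
  A <- base$coupling
  p <- dim(A)[3L]; n <- dim(A)[1L]
  # subject-identity rewiring: each subject swaps a fraction of the template
  # edges for idiosyncratic ones, so subjects differ stably in topology (the
  # between-subject variance that test-retest reliability measures)
  if (rewire_frac > 0) {
    allowed <- allowed_cells(n)
    Eoff <- apply(A != 0, c(1, 2), any) & diag(n) == 0
    have <- intersect(which(Eoff), allowed)
    free <- setdiff(allowed, which(Eoff))
    n_rw <- min(round(rewire_frac * length(have)), length(free))
    if (n_rw > 0) {
      strength <- stats::median(abs(A[A != 0 & rep(diag(n) == 0, p)]))
      drop <- sample_idx(have, n_rw)
      add <- sample_idx(free, n_rw)
      for (k in seq_len(p)) {
        Ak <- A[, , k]; Ak[drop] <- 0; A[, , k] <- Ak
      }
      for (cell in add) {
        lag <- sample(seq_len(min(2L, p)), 1)
        A[cell + (lag - 1L) * n * n] <- strength * sample(c(-1, 1), 1) *
          stats::runif(1, 0.7, 1.3)
      }
    }
  }
  off_idx <- which(A != 0 & rep(diag(n) == 0, p))
  A[off_idx] <- A[off_idx] * (1 + stats::rnorm(length(off_idx), 0, jitter_sd))
  A <- apply_group_effect(A, effect, base$modules)
  # feed-forward coupling keeps the companion eigenvalues at the oscillator
  # poles, but guard against degenerate hand-built templates anyway
  sr <- spectral_radius(A)
  while (sr >= 0.98) {
    for (k in seq_len(p)) {
      Ak <- A[, , k]; d <- diag(Ak)
      Ak <- 0.9 * Ak; diag(Ak) <- d
      A[, , k] <- Ak
    }
    sr <- spectral_radius(A)
  }
  A <- normalize_variance(A)
  ground_truth_spec(A, noise_cov = base$noise_cov, mixing = base$mixing,
                    artifact_spec = base$artifact_spec,
                    group_effect = base$group_effect, modules = base$modules,
                    seed = seed)
}

#' Generate a two-group synthetic cohort
#'
#' Per subject, the group template's nonzero cross-channel coefficients are
#' jittered (multiplicative Gaussian, sd `jitter_sd`); subjects in the
#' exposed group additionally lose a configured fraction of coupling edges
#' (the group topology shift). One recording per subject x state is
#' simulated; artifacts are injected if the template specifies them. A
#' psychometric table is emitted whose recall score depends linearly and
#' negatively (correlation `recall_r`) on the subject's true-network
#' clustering coefficient.
#'
#' @param base a [ground_truth_spec()] group template (see
#'   [template_coupling()]); its `group_effect` entry (e.g.
#'   `list(type = "edge_removal", fraction = 0.2)`) is applied to the
#'   exposed group.
#' @param n_per_group subjects per group (>= 2; study design uses 19).
#' @param states character vector of resting states (default `c("EO","EC")`).
#' @param duration_s per-state recording length in seconds (default 250:
#'   10 s discard + 240 s analysis window).
#' @param fs sampling rate (default 500 Hz).
#' @param jitter_sd per-subject multiplicative jitter of coupling
#'   coefficients (default 0.1).
#' @param rewire_frac fraction of template edges each subject swaps for
#'   idiosyncratic edges (default 0.4). This is what gives subjects stable,
#'   distinguishable network topologies; without it all subjects share one
#'   topology and epoch-to-epoch reliability of graph indices is nil by
#'   construction.
#' @param recall_r target correlation between true clustering and the recall
#'   score (default -0.6).
#' @param groups group labels, reference first.
#' @param seed master seed for the cohort.
#' @return List with `recordings` (list of [eeg_recording()]),
#'   `subject_specs` (per-subject ground truth), `manifest` (data.frame:
#'   subject_id, group, state, seed), and `psychometrics` (data.frame with
#'   TMT-A/B, immediate memory, recall per subject).
#' @export
generate_cohort <- function(base, n_per_group = 19L, states = c("EO", "EC"),
                            duration_s = 250, fs = 500, jitter_sd = 0.1,
                            rewire_frac = 0.4, recall_r = -0.6,
                            groups = c("Control", "Miners"),
                            seed = base$seed) {
  stopifnot(n_per_group >= 2L)
  effect <- base$group_effect

  subjects <- data.frame(
    subject_id = sprintf("%s%02d", rep(c("C", "M"), each = n_per_group),
                         rep(seq_len(n_per_group), 2L)),
    group = rep(groups, each = n_per_group),
    stringsAsFactors = FALSE)

  specs <- vector("list", nrow(subjects))
  names(specs) <- subjects$subject_id
  recs <- list()
  manifest <- NULL
  for (s in seq_len(nrow(subjects))) {
    sseed <- (seed * 1000L + s) %% .Machine$integer.max
    eff <- if (subjects$group[s] == groups[2L]) effect else NULL
    specs[[s]] <- subject_spec(base, jitter_sd, eff, sseed,
                               rewire_frac = rewire_frac)
    for (st in states) {
      rseed <- (sseed * 7L + match(st, states)) %% .Machine$integer.max
      rec <- generate_mvar_recording(specs[[s]], duration_s, fs, seed = rseed,
                                     subject_id = subjects$subject_id[s],
                                     group = subjects$group[s], state = st)
      rec <- inject_artifacts(rec, specs[[s]], seed = rseed + 1L)
      recs[[paste(subjects$subject_id[s], st, sep = "_")]] <- rec
      manifest <- rbind(manifest, data.frame(
        subject_id = subjects$subject_id[s], group = subjects$group[s],
        state = st, seed = rseed, stringsAsFactors = FALSE))
    }
  }

  psych <- make_psychometrics(subjects, specs, recall_r, seed)
  list(recordings = recs, subject_specs = specs, manifest = manifest,
       psychometrics = psych)
}

# Psychometric covariates: recall is generated with a stated linear negative
# dependence on the subject's true-network clustering (z-scored), so the
# correlation-recovery stage has known ground truth; the other scores carry
# plausible group-level shifts but no engineered network dependence.
make_psychometrics <- function(subjects, specs, recall_r, seed) {
  set.seed(seed + 999L)
  cc_true <- vapply(specs, function(sp) clustering_coef(true_edge_matrix(sp)),
                    0)
  cc_z <- if (stats::sd(cc_true) > 0) as.numeric(scale(cc_true)) else
    numeric(length(cc_true))
  n <- nrow(subjects)
  noise <- stats::rnorm(n)
  recall_z <- recall_r * cc_z + sqrt(1 - recall_r^2) * noise
  miners <- subjects$group == unique(subjects$group)[2L]
  data.frame(
    subject_id = subjects$subject_id,
    group = subjects$group,
    tmt_a = 28.6 + 6.2 * miners + stats::rnorm(n, 0, 7),
    tmt_b = 62.6 + 24.6 * miners + stats::rnorm(n, 0, 22),
    immediate_memory = 7.2 - 1.9 * miners + stats::rnorm(n, 0, 1.5),
    recall = 13.3 - 2.3 * miners + 1.8 * recall_z,
    true_clustering = cc_true,
    stringsAsFactors = FALSE)
}

#' Write a cohort to disk (EDF recordings + JSON ground truth + CSV manifest)
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- cohort$manifest
  man$file <- sprintf("%s_%s.edf", man$subject_id, man$state)
  for (i in seq_len(nrow(man)))
    write_edf(cohort$recordings[[paste(man$subject_id[i], man$state[i], sep = "_")]],
              file.path(dir, man$file[i]))
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  utils::write.csv(cohort$psychometrics, file.path(dir, "psychometrics.csv"),
                   row.names = FALSE)
  gt <- lapply(cohort$subject_specs, function(sp) list(
    coupling = sp$coupling, mvar_order = sp$mvar_order,
    spectral_radius = sp$spectral_radius, seed = sp$seed))
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
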