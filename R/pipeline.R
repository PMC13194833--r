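# Orchestration: simulate -> preprocess -> connectivity -> network -> graph
# indices -> ICC screening -> LME + FDR -> psychometric correlations, for
# every (measure x cleaning) combination, from one seeded config.

#' Default pipeline configuration
#'
#' Returns the full configuration list with the study-design defaults:
#' 2 x 19 subjects, EO/EC states, 250-s recordings at 500 Hz epoched into
#' 40 six-second epochs after a 10-s discard; ASR (cutoff 5, 0.5-s windows,
#' 50% overlap, maxdims 0.66) and ICA (|excess kurtosis| > 1.25, 4 SD
#' amplitude) cleaners; DTF/iCOH/wPLI estimators with MVAR order search
#' 1-30; MST-seeded 15% density binarization; ICC screening at 0.60; FDR
#' alpha 0.05. Any entry can be overridden via `...`.
#'
#' @param ... named overrides of top-level entries.
#' @return Named list (class `pipeline_config`).
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 1L,
    n_per_group = 19L,
    states = c("EO", "EC"),
    duration_s = 250,
    fs = 500,
    discard_s = 10,
    epoch_s = 6,
    analysis_s = 240,
    bands = c("delta", "theta", "alpha", "beta", "gamma", "full"),
    measures = c("DTF", "iCOH", "wPLI"),
    cleaners = c("ASR", "ICA"),
    density = 0.15,
    icc_threshold = 0.60,
    fdr_alpha = 0.05,
    mvar = list(p_min = 1L, p_max = 30L),
    welch = list(seg_s = 1, overlap = 0.5),
    asr = list(cutoff = 5, window_s = 0.5, overlap = 0.5, maxdims = 0.66,
               mode = "multichannel"),
    ica = list(kurtosis_thresh = 1.25, amp_thresh_sd = 4),
    cohort = list(jitter_sd = 0.1, rewire_frac = 0.4, recall_r = -0.6,
                  group_effect = list(type = "desegregation", fraction = 0.75),
                  mixing_strength = 0.1,
                  artifacts = list(line = list(amplitude = 5),
                                   blink = list(rate = 0.2, amplitude = 60),
                                   emg = list(rate = 0.1, amplitude = 15))),
    out_dir = NULL)
  over <- list(...)
  for (nm in names(over)) cfg[[nm]] <- over[[nm]]
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Entries present in the file override the defaults; everything else keeps
#' its default, so configs round-trip through serialization unchanged.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  over <- yaml::read_yaml(path)
  do.call(default_config, over)
}

#' Simulate the configured cohort
#'
#' Builds the group template ([template_coupling()] with the configured
#' mixing and artifacts) and generates the full cohort.
#'
#' @param cfg a `pipeline_config`.
#' @return See [generate_cohort()].
#' @export
simulate_cohort <- function(cfg) {
  tpl <- template_coupling(seed = cfg$seed)
  base <- ground_truth_spec(
    tpl$coupling,
    mixing = default_mixing(tpl$n_channels, cfg$cohort$mixing_strength,
                            falloff = 1),
    modules = tpl$modules,
    artifact_spec = cfg$cohort$artifacts,
    group_effect = cfg$cohort$group_effect,
    seed = cfg$seed)
  rw <- cfg$cohort$rewire_frac
  generate_cohort(base, n_per_group = cfg$n_per_group, states = cfg$states,
                  duration_s = cfg$duration_s, fs = cfg$fs,
                  jitter_sd = cfg$cohort$jitter_sd,
                  rewire_frac = if (is.null(rw)) 0.4 else rw,
                  recall_r = cfg$cohort$recall_r, seed = cfg$seed)
}

clean_epoch <- function(ep, cleaner, cfg, seed) {
  switch(cleaner,
         ASR = asr_clean(ep, cutoff = cfg$asr$cutoff,
                         window_s = cfg$asr$window_s,
                         overlap = cfg$asr$overlap,
                         maxdims = cfg$asr$maxdims, mode = cfg$asr$mode),
         ICA = ica_clean(ep, kurtosis_thresh = cfg$ica$kurtosis_thresh,
                         amp_thresh_sd = cfg$ica$amp_thresh_sd, seed = seed),
         none = ep,
         stop("unknown cleaner: ", cleaner))
}

# Connectivity for one cleaned full-band epoch, all measures x bands.
# DTF comes from one broadband MVAR fit, band-resolved through H(f); iCOH
# and wPLI come from one broadband Welch cross-spectrum, band-averaged.
epoch_connectivity <- function(ep, cfg) {
  out <- list()
  if ("DTF" %in% cfg$measures) {
    m <- fit_mvar(ep, cfg$mvar$p_min, cfg$mvar$p_max)
    H <- transfer_matrix(m)
    for (b in cfg$bands) out[[paste("DTF", b, sep = ".")]] <- dtf(H, b)
  }
  if (any(c("iCOH", "wPLI") %in% cfg$measures)) {
    S <- cross_spectrum(ep, cfg$welch$seg_s, cfg$welch$overlap,
                        keep_segments = "wPLI" %in% cfg$measures)
    for (b in cfg$bands) {
      if ("iCOH" %in% cfg$measures)
        out[[paste("iCOH", b, sep = ".")]] <- icoh(S, b)
      if ("wPLI" %in% cfg$measures)
        out[[paste("wPLI", b, sep = ".")]] <- wpli(S, b)
    }
  }
  out
}

binarize_cm <- function(cm, density) {
  if (cm$directed) mst_density_threshold_directed(cm, density)
  else proportional_threshold_symmetric(cm, density)
}

#' Run the full analysis pipeline
#'
#' Executes every stage for every (measure x cleaning) combination and
#' returns the three result tables: the ICC reliability grid, the screened
#' LME group-difference table (with BH-FDR and Cohen's f2), and the
#' psychometric correlation table for the exposed group. Also returns the
#' epoch-level index long table, power ratios per cleaner, and the cohort
#' manifest. All randomness derives from `cfg$seed`. If `cfg$out_dir` is
#' set, the tables are written there as CSV.
#'
#' @param cfg a `pipeline_config` (see [default_config()]).
#' @param cohort optionally, a pre-generated cohort (as from
#'   [simulate_cohort()]); by default one is simulated from the config.
#' @param progress print stage progress (default FALSE).
#' @return List with `indices` (long table), `reliability`, `lme`,
#'   `correlations`, `power_ratios`, `manifest`, `config`.
#' @export
run_pipeline <- function(cfg = default_config(), cohort = NULL,
                         progress = FALSE) {
  say <- function(...) if (progress) message(sprintf(...))
  if (is.null(cohort)) {
    say("simulating cohort (seed %d)", cfg$seed)
    cohort <- simulate_cohort(cfg)
  }
  say("processing %d recordings", length(cohort$recordings))

  rows <- list()
  pr_rows <- list()
  for (rec_name in names(cohort$recordings)) {
    rec <- cohort$recordings[[rec_name]]
    epochs <- epoch_recording(rec, cfg$discard_s, cfg$epoch_s, cfg$analysis_s)
    for (ep in epochs) {
      ep_f <- apply_filter_chain(ep, "full")
      ep_seed <- (cfg$seed * 100003L + ep$index * 131L +
                    sum(utf8ToInt(rec_name))) %% .Machine$integer.max
      for (cl in cfg$cleaners) {
        ep_c <- clean_epoch(ep_f, cl, cfg, seed = ep_seed)
        pr_rows[[length(pr_rows) + 1L]] <- data.frame(
          subject_id = ep$subject_id, group = ep$group, state = ep$state,
          epoch = ep$index, cleaner = cl,
          channel = rownames(rec$data),
          ratio = as.numeric(power_ratio(ep_c, ep_f)),
          stringsAsFactors = FALSE)
        conns <- epoch_connectivity(ep_c, cfg)
        for (nm in names(conns)) {
          bn <- binarize_cm(conns[[nm]], cfg$density)
          gi <- graph_indices(bn, seed = cfg$seed)
          mb <- strsplit(nm, ".", fixed = TRUE)[[1L]]
          rows[[length(rows) + 1L]] <- data.frame(
            subject_id = ep$subject_id, group = ep$group, state = ep$state,
            cleaner = cl, measure = mb[1L], band = mb[2L],
            epoch = ep$index, index_name = names(gi), value = as.numeric(gi),
            stringsAsFactors = FALSE)
        }
      }
    }
    say("  done %s", rec_name)
  }
  indices <- do.call(rbind, rows)
  power_ratios <- do.call(rbind, pr_rows)

  say("reliability screening")
  reliability <- icc_grid(indices, cfg$icc_threshold)
  say("group inference")
  lme_tab <- lme_table(indices, reliability, cfg)
  say("psychometric correlations")
  cors <- pipeline_correlations(indices, cohort$psychometrics, cfg)

  res <- list(indices = indices, reliability = reliability, lme = lme_tab,
              correlations = cors, power_ratios = power_ratios,
              manifest = cohort$manifest, config = cfg)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in c("indices", "reliability", "lme", "correlations",
                 "power_ratios", "manifest"))
      utils::write.csv(res[[nm]], file.path(cfg$out_dir, paste0(nm, ".csv")),
                       row.names = FALSE)
  }
  res
}

# ICC grid: one cell per group x state x cleaner x measure x band x index,
# epochs as raters, subjects as targets
icc_grid <- function(indices, threshold) {
  cells <- unique(indices[c("group", "state", "cleaner", "measure", "band",
                            "index_name")])
  rownames(cells) <- NULL
  cells$icc <- NA_real_
  cells$label <- NA_character_
  for (r in seq_len(nrow(cells))) {
    sub <- merge(indices, cells[r, 1:6])
    if (any(is.na(sub$value))) { cells$icc[r] <- NA_real_; next }
    M <- stats::xtabs(value ~ epoch + subject_id, data = sub)
    cells$icc[r] <- icc_3k(as.matrix(M))
    cells$label[r] <- classify_icc(cells$icc[r])
  }
  cells$acceptable <- !is.na(cells$icc) & cells$icc >= threshold
  cells
}

# a cell enters LME testing only if every group reached acceptable ICC
screened_cells <- function(reliability) {
  agg <- stats::aggregate(acceptable ~ state + cleaner + measure + band +
                            index_name, data = reliability, FUN = all)
  agg[agg$acceptable, setdiff(names(agg), "acceptable"), drop = FALSE]
}

lme_table <- function(indices, reliability, cfg) {
  cells <- screened_cells(reliability)
  if (!nrow(cells)) return(cells)
  out <- NULL
  for (r in seq_len(nrow(cells))) {
    sub <- merge(indices, cells[r, ])
    if (any(is.na(sub$value))) next
    t <- data.frame(Value = sub$value, Group = sub$group,
                    Subject = sub$subject_id, Epoch = sub$epoch)
    fit <- fit_group_lme(t, reference = "Control")
    out <- rbind(out, cbind(cells[r, ], data.frame(
      beta0 = fit$beta0, beta1 = fit$beta1, ci_lo = fit$ci[1L],
      ci_hi = fit$ci[2L], p = fit$p_value, f2 = fit$f2,
      sigma_u2 = fit$sigma_u2, sigma2 = fit$sigma2,
      singular = fit$singular)))
  }
  if (is.null(out)) return(cells[0, ])
  rownames(out) <- NULL
  out$p_fdr <- fdr_bh(out$p)
  out$significant <- out$p_fdr <= cfg$fdr_alpha
  out
}

# correlations within the exposed group: per-subject epoch-mean of each
# screened (cleaner, measure, state, band, index) against psychometrics
pipeline_correlations <- function(indices, psych, cfg) {
  miners <- indices[indices$group != "Control", ]
  if (!nrow(miners)) return(NULL)
  key <- paste(miners$cleaner, miners$measure, miners$state, miners$band,
               miners$index_name, sep = ".")
  means <- stats::aggregate(list(value = miners$value),
                            by = list(subject_id = miners$subject_id,
                                      cell = key), FUN = mean)
  wide <- stats::reshape(means, idvar = "subject_id", timevar = "cell",
                         direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  if (nrow(wide) < 4L) return(NULL)   # too few subjects to correlate
  correlate_with_psychometrics(wide, psych, alpha = cfg$fdr_alpha)
}

#' Compare the two cleaning strategies by power ratios
#'
#' Runs preprocessing only (filter chain + each cleaner) over the cohort and
#' summarizes the per-state grand-averaged power-ratio distributions
#' (cleaned power / raw power over subjects x channels x epochs) with
#' quartiles, mirroring a box-plot comparison of the cleaners.
#'
#' @param cfg a `pipeline_config` with at least two cleaners.
#' @param cohort optional pre-generated cohort.
#' @return List with `ratios` (long data.frame) and `summary` (quartiles
#'   per state x cleaner).
#' @export
compare_cleaning <- function(cfg = default_config(), cohort = NULL) {
  if (length(cfg$cleaners) < 1L) stop("no cleaners configured")
  if (is.null(cohort)) cohort <- simulate_cohort(cfg)
  pr_rows <- list()
  for (rec_name in names(cohort$recordings)) {
    rec <- cohort$recordings[[rec_name]]
    epochs <- epoch_recording(rec, cfg$discard_s, cfg$epoch_s, cfg$analysis_s)
    for (ep in epochs) {
      ep_f <- apply_filter_chain(ep, "full")
      ep_seed <- (cfg$seed * 100003L + ep$index * 131L +
                    sum(utf8ToInt(rec_name))) %% .Machine$integer.max
      for (cl in cfg$cleaners) {
        ep_c <- clean_epoch(ep_f, cl, cfg, seed = ep_seed)
        pr_rows[[length(pr_rows) + 1L]] <- data.frame(
          state = ep$state, cleaner = cl, subject_id = ep$subject_id,
          epoch = ep$index, channel = rownames(rec$data),
          ratio = as.numeric(power_ratio(ep_c, ep_f)),
          stringsAsFactors = FALSE)
      }
    }
  }
  ratios <- do.call(rbind, pr_rows)
  qs <- do.call(rbind, lapply(
    split(ratios, list(ratios$state, ratios$cleaner)), function(d) {
      q <- stats::quantile(d$ratio, c(0.25, 0.5, 0.75))
      data.frame(state = d$state[1L], cleaner = d$cleaner[1L],
                 q1 = q[1L], median = q[2L], q3 = q[3L],
                 iqr = q[3L] - q[1L], stringsAsFactors = FALSE)
    }))
  rownames(qs) <- NULL
  list(ratios = ratios, summary = qs)
}
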