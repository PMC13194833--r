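# eegnetrel

Reliability-screened resting-state EEG connectivity and brain-network
analysis, with a fully synthetic, ground-truth-known cohort generator so
that every stage of the pipeline is verifiable by recovery — no data
download, no human recordings.

## Who this is for

Researchers who compare directed functional connectivity between groups
from multichannel resting-state EEG and need to know (a) whether their
estimator + preprocessing combination produces epoch-to-epoch *stable*
indices before testing group differences, and (b) whether their full
pipeline can recover a known network alteration at realistic noise levels.

## What it computes

For each 6-s epoch of a 20-channel recording, after a fixed filter chain
(50 Hz notch, 60–100 Hz Butterworth band-stop, band-pass FIR) and one of
two artifact-removal strategies (artifact subspace reconstruction, or
FastICA with kurtosis/amplitude component rejection):

- **DTF** — directed transfer function from a BIC-order-selected MVAR fit,
  `DTF[j→i](f) = |H_ij(f)|² / Σ_k |H_ik(f)|²`, so the inflow of every sink
  sums to 1 at each frequency;
- **iCOH** — the imaginary part of coherency, `Im(S_ij/√(S_ii S_jj))`;
- **wPLI** — the weighted phase lag index,
  `|E Im(S_ij)| / E |Im(S_ij)|` over Welch segments;

each band-averaged (delta/theta/alpha/beta/gamma/full), binarized by
MST-seeded fixed-density thresholding (15% density ⇒ exactly 57 directed
edges on 20 channels, weakly connected by construction), and summarized by
six directed graph indices: modularity **Q**, global efficiency **GE**,
local efficiency **LE**, clustering coefficient **CC**, transitivity **T**
and out–in degree assortativity **R**.

Indices are screened by **ICC(3,k)** test–retest reliability across the 40
epochs (epochs as raters, subjects as targets; acceptable ≥ 0.60), and the
surviving cells are tested with a random-intercept linear mixed model
`Value ~ Group + (1 | Subject)` with Benjamini–Hochberg FDR correction and
Cohen's f² effect sizes, plus Pearson correlations against psychometric
scores.

The synthetic cohort generator produces two groups of 19 subjects × 2
resting states with prescribed MVAR coupling, zero-lag volume-conduction
mixing, 50 Hz line noise, blink and EMG artifacts, a controlled
"desegregation" topology shift in the exposed group, and psychometric
scores with a planted correlation to true network clustering.

## Worked example

```r
library(eegnetrel)

cfg <- default_config(
  seed = 20, n_per_group = 19, states = "EC",
  duration_s = 130, analysis_s = 120,         # 20 epochs per subject
  bands = c("delta", "alpha", "full"),
  measures = "DTF", cleaners = "ASR",
  mvar = list(p_min = 1, p_max = 8))

res <- run_pipeline(cfg)

r <- res$reliability
r[r$index_name == "CC", c("group", "band", "icc", "label")]
#>      group  band       icc     label
#> 4  Control delta 0.4607128      fair
#> 10 Control alpha 0.8201041 excellent
#> 16 Control  full 0.8009929 excellent
#> 22  Miners delta 0.4574243      fair
#> 28  Miners alpha 0.7043269      good
#> 34  Miners  full 0.5933670      fair

res$lme[res$lme$index_name == "CC", c("band", "beta1", "p", "p_fdr", "f2")]
#>    band       beta1            p        p_fdr        f2
#> 1 alpha -0.06726436 6.360607e-24 1.590152e-23 0.5343512
```

Reading: the clustering coefficient is reliable enough to test only in the
alpha band (ICC ≥ 0.60 in *both* groups — the conjunctive screening rule),
and there the exposed group shows a lower value (β₁ < 0 is the
Miners − Control difference) that survives FDR correction with a large
effect size — the pipeline recovered the desegregation shift the generator
planted, and the screening stage shows why band-specific reliability
matters before any group claim. `res$correlations` holds the psychometric
correlation table and `compare_cleaning(cfg)` the ASR-vs-ICA power-ratio
comparison.

A thin command-line wrapper with `simulate`, `run-all` and
`compare-cleaning` subcommands lives at `inst/cli/connpipe.R`:

```sh
Rscript inst/cli/connpipe.R run-all --config cfg.yaml --seed 1 --out results/
```

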