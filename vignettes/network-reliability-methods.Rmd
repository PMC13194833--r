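---
title: "Reliability-screened EEG connectivity: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reliability-screened EEG connectivity: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem this package addresses

Resting-state EEG connectivity studies face two compounding reliability
questions before any group comparison is meaningful: whether the chosen
connectivity estimator produces stable values across repeated epochs of the
same recording, and whether the preprocessing strategy that feeds it leaves
that stability intact. This package implements, as testable components, a
complete pipeline for answering both on data with *known* ground truth:
synthetic multichannel EEG cohorts with prescribed directed coupling are
pushed through epoching, filtering and artifact removal (ASR or ICA), three
connectivity estimators (DTF, iCOH, wPLI), network binarization, six directed
graph indices, ICC(3,k) reliability screening, and finally random-intercept
mixed-model group inference with FDR correction.

Because every stage consumes the output of a generator whose coupling,
mixing and artifacts are exactly known, each stage can be validated by
recovery: closed-form transfer functions for the DTF, enumeration oracles
for the graph indices, coverage simulations for the mixed model, and an
end-to-end run in which a topology difference planted in one group must
surface in the final statistics table.

# The generative model

## Source dynamics

Each subject's 20-channel source process is a stable MVAR(3):

$$x_t = \sum_{k=1}^{3} A_k\, x_{t-k} + \varepsilon_t,\qquad
  \varepsilon_t \sim \mathcal N(0, \Sigma).$$

Every channel carries a damped stochastic oscillator (complex pole pair at
10 Hz, radius 0.8 at 500 Hz sampling), giving realistic alpha-band spectra.
Cross-channel coupling is *feed-forward*: nonzero coefficients sit strictly
below the diagonal within a bandwidth of 6 channels. This is a deliberate
structural choice: the companion matrix of a feed-forward coupling stack has
exactly the oscillator poles as eigenvalues, so the process is stable for
*any* coupling strength. Without it, coupling strong enough to dominate the
DTF's estimation noise at 6-s epochs either destabilizes the process or gets
shrunk back to insignificance by a stability-enforcement loop; with it, the
directed flow can be strong (nominal coefficient 0.5) and the model remains
exactly within the class the DTF assumes. A similarity transform
(`normalize_variance()`) equalizes the stationary channel variances, which a
chain of strong feed-forward couplings would otherwise spread over orders of
magnitude.

Channels are organized in four 5-channel modules, with denser coupling
inside modules (edge probability 0.9) than between (0.35), so segregation
indices (Q, CC, T) have genuine structure to measure.

## Subject identity and the group effect

Test-retest reliability across epochs is only meaningful if subjects differ
in a stable way; the ICC's numerator *is* between-subject variance. Each
subject therefore swaps 40% of the template's coupling edges for
idiosyncratic ones (within the allowed feed-forward band) and jitters the
surviving coefficients by 10% multiplicative Gaussian noise. With these
defaults the DTF-derived indices reach intraclass correlations in the
good-to-excellent range, which is the regime the screening rule is designed
to operate in; removing the rewiring makes all subjects statistically
identical and drives every ICC to zero or below — a useful negative control,
not a useful cohort.

The exposed group ("Miners") receives a *desegregation* shift: 75% of
within-module coupling edges are rewired to random cross-module positions,
preserving edge count while dismantling modular structure. This is the
package's operationalization of reduced network segregation, and it lowers
clustering, modularity and transitivity of the true network by construction.
A plain `edge_removal` effect (delete a fraction of edges) is also
available; note that at *fixed network density* the downstream effect of
random deletion on clustering is sign-unstable, because the thresholding
stage refills the freed slots with whatever edges come next — this is why
desegregation is the default mechanism for planting a clustering reduction.

The effect fraction of 0.75 was chosen so that the recovered group effect
sizes for clustering at the default scaled-down run fall in the
medium-to-large Cohen's f² band typical of significant sensor-level
resting-state group differences. The template's ~48 true coupling
edges are deliberately commensurate with the 57 edges the default 15%
density threshold retains, so the binarization boundary falls among
genuine edges; with far fewer true edges the boundary sits in the
estimation-noise floor and per-epoch networks stop carrying subject or
group structure.

## Volume conduction and artifacts

Zero-lag mixing is modeled by a unit-diagonal matrix whose off-diagonal
weights decay exponentially with channel index distance (peak 0.1, falloff
1.0). Mixing strength deserves comment: instantaneous mixing leaves phase
relations untouched (the basis of iCOH's and wPLI's robustness) but does
distort DTF *magnitudes*, since the observed transfer matrix becomes
\(M H(f)\). At mixing strengths around 0.25 the banded leakage structure of
\(M\) dominates the fixed-density edge ranking and the thresholded networks
reflect the montage, not the coupling; 0.1 keeps a visible
volume-conduction surrogate while letting true coupling win the ranking.

Artifacts are scripted templates with controlled rates: a 50 Hz sinusoid on
all channels, frontally weighted 0.4-s raised-cosine-squared blink bumps at
Poisson onsets, and 60–100 Hz band-passed, Hann-enveloped 0.3-s EMG bursts
on random channel subsets. Only their statistical and spectral signatures
matter to the cleaners, so no attempt is made at biophysical realism beyond
that.

The psychometric table generates recall scores with a fixed linear
dependence (r = −0.6) on the subject's true-network clustering, so the
correlation stage has a recoverable planted signal; the remaining scores
carry group-level shifts only.

# Preprocessing

Epoching discards the first 10 s and cuts the following 240 s into 40
non-overlapping 6-s epochs (all three durations configurable). The filter
chain applies, in order: a 50 Hz notch (RBJ biquad, Q = 35, forward–backward
so zero-phase), a 4th-order Butterworth band-stop at 60–100 Hz
(zero-phase), and a linear-phase FIR band-pass at the analysis band edges
(Kaiser design, 80 dB stop-band target, transition width 25% of the lower
edge with a 1 Hz floor; applied by FFT convolution with group-delay
compensation). Zero-phase application throughout protects the phase-based
estimators. Band edges default to delta 0.5–4, theta 4–8, alpha 8–13, beta
13–30, gamma 30–60, full 0.5–60 Hz; band aggregation uses half-open
intervals \([lo, hi)\) so adjacent bands never share a frequency bin.

ASR estimates one reference covariance per 6-s epoch, eigendecomposes it,
and slides 0.5-s windows at 50% overlap through the eigenspace. A window is
flagged when its eigenspace variance exceeds the mean eigenvalue plus 5
eigenvalue standard deviations; flagged windows are reconstructed with
their high-variance components projected out, always retaining at least
`floor(0.66 * n_channels)` dimensions, and windows are reassembled by
raised-cosine overlap-add so unflagged stretches pass through bit-true. The
flag statistic is the window's *mean* component variance: flagging on any
single component's variance would fire constantly on stationary data
(per-component window variance has roughly 10% relative spread at these
window lengths), which would contradict the intended behavior that clean
epochs pass unchanged. A single-channel variant (`mode = "per-channel"`)
screens each channel against its own window-variance distribution, with a
median/MAD threshold because a large burst would otherwise inflate the
mean-and-SD rule enough to mask itself.

ICA cleaning uses an in-package FastICA (symmetric decorrelation, tanh
contrast, seeded random initialization). Components are rejected when their
absolute *excess* kurtosis exceeds 1.25 — the threshold is read as excess
kurtosis because a raw-kurtosis reading of 1.25 would reject every
component, Gaussian ones included — or when their peak amplitude exceeds 4
component standard deviations. One behavior is worth knowing: on epochs
whose sources are all near-Gaussian (the synthetic cohorts without
artifacts), the ICA rotation is mathematically unidentifiable and the
fixed-point iteration cannot converge; after its retry budget the
decomposition returns the best iterate, flagged `ica_converged = FALSE`,
rather than failing, since in that regime every orthogonal rotation is an
equally valid decomposition. A strict erroring mode is available. The
4-SD amplitude rule is worth watching on strongly oscillatory data: waxing
and waning alpha envelopes reach 5 SD peaks without being artifacts, so on
such data the ICA arm removes genuine signal power — which is precisely the
kind of preprocessing-induced difference the power-ratio comparison
(`compare_cleaning()`) is there to expose.

# Connectivity estimation

**DTF.** Each cleaned full-band epoch is fitted with an MVAR model by
conditional least squares on a common sample window, with BIC order
selection over a configurable range (default 1–30; the BIC is
\(\log\det\hat\Sigma + \frac{\log N}{N}\,p\,n^2\)) and unstable candidates
excluded by the companion-eigenvalue criterion. The transfer matrix
\(H(f) = [I - \sum_k A_k e^{-i2\pi f k/f_s}]^{-1}\) is evaluated on a
0.5–60 Hz grid at 0.5 Hz spacing, and

$$\mathrm{DTF}_{j\to i}(f) \;=\;
  \frac{|H_{ij}(f)|^2}{\sum_{k} |H_{ik}(f)|^2},$$

i.e. normalized over all sources flowing into sink *i*, which forces the
inflow of every sink to sum to one at every bin (asserted to 1e-10 in the
tests) and bounds values in [0, 1]. Band values are arithmetic means over
the band's bins. DTF is computed from broadband epochs and band-resolved
through \(H(f)\), never from band-pass-filtered epochs: MVAR fitting on
narrowband signals is ill-conditioned, and frequency selectivity is already
explicit in \(f\).

**iCOH and wPLI.** Both come from Hann-windowed Welch cross-spectra (1-s
segments, 50% overlap, so 11 segments per 6-s epoch). iCOH is the absolute
imaginary part of the coherency, band-averaged. wPLI is
\(|E[\mathrm{Im}\,S_{ij}]| / E[|\mathrm{Im}\,S_{ij}|]\) with the
expectation over the Welch segments within the epoch — the intra-epoch
reading is forced by the fact that the pipeline computes wPLI per epoch — and
pairs whose imaginary cross-spectrum vanishes identically are defined as 0.
A debiased squared variant is available. Both estimators ignore zero-lag
correlations by construction; the test suite demonstrates the contrast by
mixing two independent sources instantaneously, which drives coherence
magnitude above 0.5 while iCOH and wPLI stay below 0.05 (the residual being
the finite-segment positive bias of order \(1/\sqrt{n_{\mathrm{seg}}}\),
which is why that demonstration uses long constructions).

# Network construction

Directed (DTF) matrices are binarized in two tiers: the weights are
symmetrized by the pairwise maximum and inverted so a minimum-spanning-tree
search (deterministic Kruskal, ties broken lexicographically on source then
sink index) finds the tree of strongest connections; for each tree link the
directed edge attaining the maximum is seeded; then the strongest remaining
directed edges are added until exactly `round(density * n(n-1))` edges
(round half up) are present. The result is weakly connected by
construction, and at the default 15% density on 20 channels has exactly 57
edges for every subject and epoch — identical edge count across subjects is
what makes the graph indices comparable. Symmetric matrices (iCOH, wPLI)
follow the same tree-then-strongest-edges recipe on undirected edges
(29 edges at 15% on 20 channels, round half up of 28.5). Raising the
density never removes an edge (nested edge sets under the fixed
tie-break), and the spanning tree is always present. A legacy
fraction-of-maximum threshold (60% of the peak weight) is exposed as
`threshold_fraction_of_max()` for comparison; it controls neither density
nor connectivity and makes no acceptance claims.

# Graph indices

All six indices use the directed conventions of the binary brain-network
literature: Newman directed modularity
\(Q = \frac 1m \sum_{ij} (A_{ij} - k_i^{out} k_j^{in}/m)\,
\delta(c_i, c_j)\); global efficiency as the mean inverse shortest directed
path length (unreachable pairs contribute zero; BFS distances); local
efficiency as the mean over nodes of the global efficiency of the subgraph
induced on the node's in- and out-neighbors; Fagiolo directed clustering
\(t_i = \frac12 [ (A + A^T)^3 ]_{ii}\) over
\(k^{tot}_i (k^{tot}_i - 1) - 2 k^\leftrightarrow_i\), with zero-denominator
nodes contributing 0 so the mean always runs over all *n* nodes;
transitivity as total triangles over total connected triplets; and
assortativity as the Pearson correlation of source out-degree and target
in-degree over directed edges, returned as flagged `NA` when a degree
sequence is constant (e.g. the complete digraph).

Modularity search is exact for networks up to 8 nodes (enumeration over all
set partitions via restricted growth strings) and switches to seeded greedy
agglomeration on the community-aggregated gain matrix, followed by local
node moves, with 20 restarts, above that. The exact mode exists because the
package's correctness contract for small graphs is equality with an
enumeration oracle to 1e-12, which no greedy heuristic can promise; the
greedy mode exists because Bell(20) is astronomically beyond enumeration.
Both optimize the same printed objective, and on 6-node graphs (above the
default exact cutoff, checked against enumeration in the tests) the greedy
search attains the exact optimum.

# Reliability screening and inference

ICC(3,k) — two-way mixed, consistency, average measures — is computed from
the two-way ANOVA mean squares of the epochs-by-subjects grid:
\((\mathrm{BMS} - \mathrm{EMS})/\mathrm{BMS}\), with epochs as raters
(k = 40 at full scale) and subjects as targets. Values are reported as
computed, including negative ones (flagged, binned as poor); bins are poor
< 0.40 ≤ fair < 0.60 ≤ good < 0.75 ≤ excellent. A cell enters group
testing only if *every* group reaches ICC ≥ 0.60 — the screening rule is
deliberately conjunctive, since a measure unreliable in either group cannot
support a between-group claim. One caveat the null simulations make
explicit: for small target counts the null ICC(3,k) is biased negative
(roughly \(-2/(n_{\mathrm{targets}}-3)\)), so "centered near zero" checks
use many targets.

The group model is `Value ~ Group + (1 | Subject)` fitted by REML
(`lme4`), with Control as the reference level, a Wald 95% CI on the group
coefficient, and a Wald z p-value by default (Satterthwaite via `lmerTest`
is a documented option; the default is the cheaper one because the
balanced designs here have hundreds of error degrees of freedom, where the
two coincide to the digits reported). Singular fits (\(\sigma_u^2 \to 0\))
are retained and flagged. Cohen's f² is built from the marginal R²
(fixed-effect variance over fixed + random intercept + residual), the
standard construction when the model is a mixed model. BH-FDR is applied
once over the whole family of state-band-index tests. Pearson correlations
of the exposed group's per-subject epoch-mean indices against the
psychometric columns are FDR-corrected as one family; the pooled-variance
t-test from printed summary statistics (`t_from_summary()`) reproduces
demographic-table rows exactly.

# Problem sizes used by the checks

The test-suite and acceptance-script runs are scaled to desk hardware as
the package's own choice of problem sizes: order-recovery and
direction-recovery use 100 seeded 6-s epochs; the metric oracle sweep runs
all 4,160 digraphs on 3–4 nodes plus 200 random 5-node digraphs; LME
coverage and null calibration use 500 replicates of the full 19+19×40
design at the stated effect (β₁ = −0.01, σ_u = 0.005, σ = 0.01); the
end-to-end recovery keeps the full 19+19 cohort (the subject dimension is
what powers a between-group test) and scales the recording length to 20
six-second epochs of one state, analyzed with DTF + ASR in the delta, alpha
and full bands.

# What passing tests do and do not show

The generator produces exactly the model class the DTF assumes (linear,
stationary, Gaussian MVAR with instantaneous mixing), plus scripted
artifacts. Passing recovery tests therefore validates the *implementation*
of every stage and the *logic* of the screening-then-inference design. They
do not certify behavior on real EEG, which is nonstationary and
non-Gaussian, whose volume conduction is not a fixed banded matrix, and
whose artifacts do not follow templates; nor do they validate sensor-level
connectivity against source-level truth. The feed-forward coupling
structure, chosen for unconditional stability, also means the synthetic
data contain no feedback loops — estimators are never tested here against
bidirectional coupling at a single pair, and the "direction recovery"
results should be read accordingly.

# Known limitations

Single fixed montage ordering for the mixing surrogate; no channel
interpolation, re-referencing or bad-channel logic (out of scope by
design); greedy modularity above 8 nodes is a heuristic with seeded
restarts, not a certificate; wPLI at few segments carries its documented
positive bias; and the EDF writer targets the minimal subset of the format
needed to round-trip the synthetic cohorts (16-bit, uniform rate, 1-s
records).
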