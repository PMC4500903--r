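---
title: "Sliding-window dynamic connectivity: model, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sliding-window dynamic connectivity: model, estimators, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynfc)
```

## The problem

Static functional connectivity reduces each pair of brain regions to a
single correlation over the whole recording. Dynamic analyses instead
track a correlation *time-series* per edge and must then decide at which
time-points an edge is "present". Two defensible rules exist: select
windows where the correlation magnitude exceeds a global cutoff, or
select windows where an edge rises above its own typical level
(mean + k·SD). Which rule is appropriate depends on how the temporal
mean and temporal variance of edge correlations relate to each other
across the connectome — the question this package's statistics answer.

## Estimators

### Sliding-window correlation

For an N × T series at sampling interval TR, window position t
(1-based) covers samples t … t+w−1; the window slides in steps of one
sample, so W = T − w + 1 positions exist. A 240-sample recording with a
45-sample window therefore yields 196 windows — a window starting later
than position 196 would run past the end of the data, so no value is
emitted for those positions. At each position the correlation of every
node pair is computed: Spearman's rank coefficient by default (robust to
outliers in short windows; ties receive average ranks, the standard
convention, which also makes the brute-force oracle in the test-suite
well defined), or Pearson's coefficient. Storage is edge-major
(E × W, E = N(N−1)/2, upper-triangle row-major order with i < j), which
halves the memory of the N × N × W cube and keeps each edge's
trajectory contiguous for the per-edge statistics;
`as_connectivity_matrix()` reconstructs the symmetric per-window view.

A window in which a node's segment is constant has no defined
correlation. Such values are stored as `NA`, counted on the
`edge_series` object, and excluded from all downstream summaries rather
than silently imputed.

### Edge summaries and the scaling test

Each edge is reduced to its temporal mean and unbiased (n − 1) sample
variance over non-missing windows. The n − 1 estimator was chosen
because window counts are modest (~200) and per-edge; the
bounded-variable variance bound used as a run-time invariant,
σ² ≤ (1 − μ)(1 + μ)·n/(n − 1), carries the matching correction factor.

The order of operations for the group-level scaling test is: summarise
each subject, average the per-edge means and variances across subjects,
then compute one Spearman rank correlation ρ between the E group-level
(μ, σ²) pairs. Averaging before correlating (rather than averaging
per-subject correlations) matches the procedure the statistic is meant
to mirror; a pooled alternative — correlating all subject-level pairs at
once — can be had by concatenating subject summaries into one
`edge_summary`, but is not the default. The two-sided p-value uses the
t approximation with E − 2 degrees of freedom, appropriate because E is
large (tens of thousands at whole-brain scale, hundreds in the synthetic
cohorts); an exact permutation p-value is available for E ≤ 9, which is
only useful in toy settings.

### Thresholding

Both strategies use strict inequality (">"): this makes the
zero-variance edge unambiguous (a constant trajectory never exceeds its
own mean) and keeps "greater than the mean plus k SD" literal.
Thresholds apply to signed correlations by default — the motivating
examples are positive-valued — with an `absolute` option on the
magnitude rule. The operational core of the two-strategy distinction is
exact, not statistical: adding a constant to one edge's trajectory
changes its magnitude raster but leaves its variance raster bit-for-bit
unchanged, and the test-suite asserts exactly that.

### Network contrast

Edges are "within" iff both endpoints share a partition label. Per
subject, σ²\_e is averaged over each class with every edge weighted
equally (no per-network size normalisation), and the two per-subject
class means are compared with a **paired** two-tailed t-test: both means
come from the same subject, which makes pairing the natural reading; an
unpaired Welch option is exposed. The t statistic is reported for
within − between, so a negative value means within-network edges vary
less. Two degenerate cases are defined rather than left to error: an
all-zero difference vector reports t = 0, p = 1, and a constant non-zero
difference vector is flagged `degenerate` instead of reporting an
infinite t.

## The synthetic generator

Real resting-state data for this analysis is an external download, so
the generator is a first-class module, not a fixture. Node i in block k
is mixed from latent unit-variance series:

x_i(t) = a_k(t)·g_k(t) + b(t)·h(t) + √(1 − a_k(t)² − b(t)²)·ε_i(t)

giving instantaneous correlations a_k(t)² + b(t)² within block k and
b(t)² between blocks — closed forms returned as ground truth. The
defaults define the study conditions used throughout the tests: 20
subjects, 40 nodes in 4 equal blocks, T = 240 samples at TR = 2 s,
constant within-block coupling a = 0.8, and shared coupling
b(t) = 0.3 + 0.2·sin(2πt/200). These were chosen once to give (i) a
clearly segregated block structure (within-block correlation ≈ 0.73 on
average), (ii) genuine slow connectivity dynamics (period 200 samples,
more than four window lengths at w = 45, so windowed estimates can track
them), and (iii) feasibility a² + b² ≤ 0.89 < 1 at every sample.

Latent series are white Gaussian noise passed through a second-order
Butterworth band-pass (default 0.008–0.1 Hz, the conventional
resting-state band) applied forwards and backwards (`signal::filtfilt`,
zero phase) and re-standardized. This gives BOLD-like autocorrelation
without modelling hemodynamics. Each output node series is standardized
to zero mean and unit sample variance; correlations — windowed, ranked
or product-moment — are invariant to this affine rescaling, so the
standardization contract costs nothing downstream.

Determinism: the cohort seed initialises one stream from which one
sub-seed per subject is drawn up front, so subject s is bit-identical
regardless of how many subjects follow it.

What the generator does **not** emulate: hemodynamic response
convolution, head motion, physiological noise, scanner drift, spatial
structure of parcels, or negative between-network coupling. Passing
tests on this cohort therefore demonstrates correctness of the
estimators and the direction of the designed effects under a plausible
correlation structure — not that real fMRI will show any particular
effect size.

### The idealized two-trajectory example

`figure1_sinusoids()` builds the canonical illustration of the two
strategies: S1 with high mean and small fluctuation (mean 0.26,
amplitude 0.05) and S2 centred on zero with larger fluctuation (mean 0,
amplitude 0.2), in anti-phase, over 240 samples with period 80 (three
full cycles, so temporal means are exact). S2's parameters are fixed by
the quoted −0.2…0.2 range; S1's are not stated anywhere, so values were
chosen to reproduce the qualitative binarization pattern under the
caption's cutoffs {0.3, 0.2, 0.15}: S1 peaks-only → throughout →
throughout, S2 absent → absent → peaks-only. (The surrounding body text
lists {0.4, 0.3, 0.2} instead; the demo follows the caption and every
cutoff is an argument.) A variance threshold of k = 1 selects the peaks
of both: for a pure sinusoid the SD is A/√2, and sin exceeds 1/√2 of its
amplitude on exactly a quarter of each cycle, the closed form the tests
check against.

## Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| `window_length` | 45 samples (90 s at TR 2 s) | samples | common rule-of-thumb window; short enough to see dynamics, long enough for a stable rank correlation |
| `method` | `"spearman"` | — | robust in short windows; `"pearson"` for the parametric replication |
| magnitude `cutoff` | demo set {0.3, 0.2, 0.15} | correlation | spans the transition of the idealized example |
| variance `k` | 1 | SD units | "one SD above its own mean"; monotone in k |
| `latent_bandpass` | 0.008–0.1 | Hz | conventional resting-state band |
| cohort couplings | a = 0.8, b = 0.3 + 0.2 sin | — | see study conditions above |

`seconds_to_samples()` refuses non-integer sample counts (90 s at
TR 2.1 s is an error, not a rounding): silent rounding would change W
and every downstream shape.

## Numerical choices and degenerate inputs

- Windows are indexed by their first sample; stride is fixed at one
  sample.
- Undefined correlations (constant segments) propagate as `NA` with
  logged counts; summaries require at least two usable windows per edge
  and name the offending edge otherwise.
- Jaccard agreement between two empty presence sets is defined as 1
  (identical sets), so "identical rasters ⇒ all Jaccard 1" holds without
  a special case.
- Network display order in `variance_matrix()` follows first appearance
  in the partition, nodes keeping their original order inside each
  network — deterministic without hidden sorting.
- Round-tripping ROI tables is bit-exact: numerics are written with 17
  significant digits.
- Pipeline manifests hash the canonical JSON form of the configuration
  and the MD5 of every output file; identical config + seed reproduces
  identical hashes.

## Problem sizes used in the checks

The packaged checks run the full pipeline at the synthetic study scale —
20 subjects × 40 nodes × 240 samples, windows of 25/45/65 samples, both
correlation methods (about 20 s total) — and verify estimator
correctness on small fixtures against brute-force oracles (explicit
average-rank Spearman, naive per-window recomputation, exhaustive edge
enumeration). Ground-truth recovery uses 10 subjects and demands a mean
absolute trajectory error of at most 0.10 under slow dynamics; the
observed error is around 0.02. The whole-brain 264-node setting is
exercised only through its exact combinatorics (34716 edges, 196
windows), which are instantaneous.

## Known limitations

- Tapered windows, strides > 1, phase- or wavelet-based connectivity
  are out of scope; the window is rectangular.
- No surrogate/null models for edge presence and no graph-theoretic
  summaries beyond raster density and overlap.
- No k-means "state" clustering; the mean–variance results bear on how
  such clustering would behave (it follows the high-variance,
  between-network dimensions), but the procedure itself is not
  implemented.
- The magnitude of the group-level scaling ρ on synthetic cohorts
  depends on the chosen coupling structure; only its sign and stability
  across windows/methods are claims the package tests.
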