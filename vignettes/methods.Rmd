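---
title: "Quantifying inhibition-dependent response variability on multi-electrode arrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying inhibition-dependent response variability on multi-electrode arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikevar)
```

## The scientific question

Cultured cortical networks on a multi-electrode array (MEA; here a 6 x 10
grid at 500 µm pitch) answer an electrical stimulus with a brief
network-wide burst. When fast GABAergic inhibition is pharmacologically
blocked, these evoked responses become strikingly stereotyped: the same
wave-like pattern, radiating from the stimulation site at roughly 0.5 m/s,
repeats trial after trial. With inhibition intact, responses to the same
stimulus are far more variable. `spikevar` implements the analysis chain
that quantifies this contrast — how much trial-to-trial variability each
condition carries, how well responses identify their stimulation source,
whether the two conditions share response structure, and how activity
propagates across the array — together with a synthetic generator that
emulates both regimes so the whole chain can be exercised and validated
without access to recordings.

The working hypothesis the pipeline is built to probe: intact-inhibition
("control") responses behave like *noisy renderings* of the stereotyped
disinhibited ("blocked") responses — inhibition acts as a network noise
source rather than reshaping the response repertoire.

## Response representations

Every analysis starts from screened 500-ms post-stimulus response windows
and uses one of four representations per trial:

* **Population rate** — all electrodes pooled, 1-ms bins over 10–500 ms,
  smoothed with a centered 5-ms moving average (491 values). The moving
  average shrinks at the window edges rather than zero-padding, so edge
  bins are means of the observations that exist.
* **Binary words** — per electrode, a 125-bit vector marking which 2-ms
  bins of the first 250 ms contain at least one spike.
* **First-spike latencies (FSL)** — per trial, the first spike time of each
  of the `k = 8` most active electrodes. Non-participating electrodes
  receive a random Uniform[10, 500] ms fill when the vectors feed a
  classifier (so missingness alone cannot drive classification) and a zero
  fill when they feed clustering; both choices are exposed.
* **Recruitment order** — the ranks of those latencies (1 = earliest).
  Ties share average ranks; missing electrodes each receive the mean of
  the unassigned ranks, so the rank sum is always `k(k+1)/2`. Ranks are
  computed from observed latencies only, never from fills, which would
  scramble them.

Electrode selection deserves a note. Electrodes are included when they fire
in at least a fixed fraction of kept trials, evaluated jointly over both
conditions so one and the same assembly is analyzed throughout, and the
most-active ranking uses the control condition only, so the disinhibited
recording cannot bias the choice. On real recordings the inclusion
threshold is 0.9. On the synthetic defaults it cannot be: the control noise
model fails each electrode wholesale in 30% of trials, which caps
participation near 0.7, so the simulated-study pipeline uses 0.6 — low
enough to include every electrode that responds whenever it does not fail
wholesale, and high enough to exclude pathologically silent channels.

## Variability: cluster content and C 1/3

Pairwise distances between same-source responses use the `1 - cos(alpha)`
metric (correlation, Euclidean and Levenshtein variants are available).
Single-linkage agglomeration — at each step the most proximal pair of
clusters merges — yields a dendrogram per network (per electrode for binary
words). Cutting the tree at a sweep of distance cutoffs (200 evenly spaced
values from 0 to the maximum merge height; a merge applies when its height
is at or below the cutoff) gives the cluster-content curve, and **C 1/3**
is the smallest cutoff at which the cluster count drops strictly below one
third of the number of responses. Low C 1/3 means the responses collapse
into few clusters at small distances, i.e. low variability. Curves that
never drop within the grid return the maximal cutoff with a flag.

Condition effects are tested with the paired Wilcoxon signed-rank test on
`control - blocked` differences (right tail: blocking shrinks C 1/3). The
test is exact for up to 25 pairs via a dynamic program over all sign
assignments of the average-ranked absolute differences — exact zeros are
dropped first, and ties do not force an approximation; larger samples use
the tie-corrected normal approximation with continuity correction. With 8
networks all shifted in one direction the one-sided p is exactly
`1/256 ≈ 0.0039`. Correlations use Spearman's rank correlation throughout;
constant input is reported as undefined rather than zero.

## Discrimination: contrast, classification, transfer

For a pair of stimulation sources, the **contrast**
`(D_out - D_in) / (D_out + D_in)` compares the summed inter-source pair
distances to the summed intra-source pair distances (intra sums of the two
sources pooled, giving one number per source pair; sums rather than means,
per the definition — with 40 trials per source the pair counts nearly
balance, and a mean-normalized variant is available). Supervised
classification uses a support-vector machine with either a Gaussian
radial-basis kernel (median-heuristic bandwidth on the training distances,
regularization constant 1 — parameter-free defaults) or a linear kernel,
50 stratified 50/50 train/test splits, accuracy reported as mean ± SD over
splits, one-vs-one voting for 4 sources (chance 0.25). Population-rate
traces under the radial-basis kernel are restricted to their 10–70 ms
segment, where the discriminative transient lives.

**Cross-condition transfer** fits the classifier entirely on one
condition and evaluates it entirely on the other. Because the synthetic
generator drives both conditions from the *same* wave templates, transfer
above chance is expected by construction — this is precisely the
shared-structure property the analysis is designed to detect.

## Propagation: conditional firing probabilities

The conditional firing probability (CFP) of an ordered electrode pair
(condition on j, observe i) is estimated at lags 0–100 ms in 2-ms steps
over all response windows; conditioning spikes near the window end
contribute only the lags that fit, with the denominator counted per lag, so
edges add no bias. Electrode pairs need at least 100 spikes on each
electrode, and profiles whose smoothed peak stays below 0.05 are excluded.
Profiles are smoothed with a zero-padded 3-point moving average: the
constant denominator means an isolated raw peak becomes a symmetric 3-lag
plateau, and the window edges cannot acquire spuriously inflated values (a
shrinking window divides edge bins by 2 and can manufacture a false lag-0
maximum). The **typical delay** is the lag of the first local maximum of
the smoothed profile; within a flat plateau the lag with the largest raw
probability wins (ties to the smaller lag), so the smoothing cannot shift
the delay of a clean single peak.

Typical delays grouped by exact inter-electrode distance give the
delay-vs-distance curve and its Spearman correlation. For a single source,
regressing retained delays on the *radial distance difference* (distance of
the observed minus the conditioning electrode from the source) recovers the
wave velocity as the inverse slope; the free intercept absorbs the lag-grid
discretization. On zero-noise wave data, every retained delay sits within
one 2-ms lag bin of the radial prediction, and the recovered velocity lands
on the configured 0.5 m/s to within a few percent.

## The synthetic generator

Each stimulation source owns a deterministic **wave template**: electrode
onset latency = 5 ms base delay + distance-from-source / velocity
(0.5 m/s), expected burst count 8 at the source decaying with a 2000-µm
length constant (`Inf` gives a source-independent envelope), and a 30-ms
burst decay constant. A trial draws, per surviving electrode, a first spike
exactly at the template onset plus Poisson-many extras at exponential
delays — the deterministic first spike makes the zero-noise limit exactly
reproduce the template's latencies and recruitment order, which anchors
several tests. Condition noise is three-parameter: independent zero-mean
Gaussian jitter on every spike time (clipped back into (0, 500], which
preserves counts), wholesale per-electrode participation failure, and a
multiplicative rate scale. Defaults encode the two regimes: control
jitter 10 ms / failure 0.3 / rate 0.5; blocked jitter 1 ms / failure 0.05 /
rate 1. The Gaussian shape is a modeling choice (a uniform variant exists in
the jitter control); 10 ms is the width that the calibration control
recovers, 0.3 is a free choice for the unquantified control failure rate.
Both conditions share templates and stimulation order; every trial owns an
RNG sub-stream derived from the master seed, so growing the trial count
never reshuffles earlier trials, and a dataset pair is byte-reproducible
from its config.

Default sources sit more than two grid steps apart; a sweep configuration
with sources at 1–7 grid steps along one row serves the
contrast-vs-separation analysis, and symmetric corner sources (whose
distance multisets coincide, making the expected population-rate trace
source-independent) serve the rate-control experiment.

What the generator does *not* emulate: spontaneous inter-stimulus
activity, biophysical membrane/synapse dynamics, seizure-like regimes,
electrode noise and spike-sorting errors, and any mechanism by which
disinhibited bursts actively erase fine source information (see
limitations). Passing tests on this generator validate the pipeline's
estimators and the directional logic of the condition comparison — not the
biological claims themselves.

## Surrogate controls

* **Jitter injection** perturbs every spike with zero-mean Gaussian noise
  of a chosen width (counts preserved; clipping, not reflection, at the
  window edges — the simplest count-preserving rule).
* **Subsampling** deletes spikes uniformly at random per electrode until
  the across-trial mean count matches the paired condition, never adding
  spikes; electrodes already at or below the target are left untouched
  with a warning.
* **Jitter calibration** jitters the blocked data at candidate widths and
  returns the width whose dispersion statistic (default: C 1/3) lands
  closest to the control value. The calibration feature defaults to
  zero-filled FSL vectors: their dispersion grows monotonically with the
  width, whereas recruitment-order dispersion saturates once the jitter
  exceeds the spread of onset latencies (~5 ms here) and can no longer
  identify the width. When the control condition is generated from the
  blocked templates with 10 ms jitter, calibration recovers a best width
  within ±30% of 10 ms over repeated simulations.

## Numerical choices and degenerate inputs

Windows are half-open `(0, 500]` (a spike at exactly 500 ms belongs to the
window; binning within it uses half-open `[t, t + dt)` bins). Cosine
distance between two zero vectors is 0, between a zero and a non-zero
vector 1, and numerical fuzz below 1e-12 is zapped so identical rows sit at
exactly 0. The participation boundary is inclusive (firing in exactly 90%
of trials qualifies). Network-spike detection merges consecutive
supra-threshold 3-ms bins into one event and searches only 400 ms post
stimulus; the threshold is exposed as configuration (the reference
algorithm is external), with 0.25 x included electrodes per bin as a
scale-aware default. Top-electrode ties break toward the lower electrode
id. All-zero difference vectors give signed-rank p = 1 with a flag;
constant inputs give an undefined Spearman correlation with a flag. The
`C 1/3` scan runs on a cutoff grid by default with an at-merge-heights
option.

Problem sizes in the shipped tests and acceptance script were chosen as the
smallest that make the directional results stable: 8 networks for the
cluster-content comparison (the study's own size), 20 simulated networks
for fraction-of-seeds statements, 40 trials per source, 50 classification
repetitions in the user-facing default and 20 in the batch runs.

## Known limitations

* The control condition is *by construction* an independently-noised copy
  of the blocked condition. Expected separability under blocked therefore
  dominates control at every source separation, and the short-range
  *reversal* (blocking worsening discrimination for adjacent sources)
  cannot arise from this noise family: the contrast difference
  blocked - control shrinks at 1-step separations but does not go
  negative. Reproducing that reversal would need a mechanism in which
  disinhibited bursts actively discard fine source information (e.g.
  convergence of adjacent wavefronts onto one intrinsic burst pathway),
  which is outside this generator's scope.
* Recruitment-order dispersion saturates under heavy jitter, so rank-based
  statistics cannot distinguish very noisy regimes from one another.
* CFP typical delays are quantized to the 2-ms lag grid; velocity
  estimates inherit that quantization.
* The participation-threshold choice interacts with the failure rate of
  the noise model (see above); analyses of real recordings should use the
  0.9 default.
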