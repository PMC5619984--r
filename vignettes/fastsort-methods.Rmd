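---
title: "Drift-tracking spike sorting: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Drift-tracking spike sorting: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(fastsort)
```

# The problem

Chronic tetrode recordings run for days to months. Over those timescales the
electrode moves relative to the tissue, so each unit's spike waveform — in
particular its amplitude — drifts slowly. Conventional spike sorters cluster
a static feature space once; as drift accumulates, clusters smear into each
other and units are lost or merged. `fastsort` implements a two-step
unsupervised pipeline that clusters *locally in time*, where waveforms are
effectively stationary, and then *links* those local clusters through time
into unit chains, so a unit is tracked through its drift rather than averaged
across it.

# Pipeline overview

1. **Spike identification.** Each acquisition segment is processed in 15 s
   blocks with 100 ms padding: a fourth-order elliptic band-pass
   (300–7500 Hz, applied forward and reverse for zero phase, 0.1 dB passband
   ripple / 40 dB stopband attenuation) followed by common-median
   referencing across channels. A threshold-crossing detector runs on the
   across-channel absolute maximum of each tetrode; after a crossing the
   event peak is the local maximum, and the detector re-arms once the signal
   stays below 3 × MAD for 8 consecutive samples. Each event yields a
   64-sample (31 + peak + 32), 4-channel snippet — a 256-dimensional vector.
2. **Step 1 — local clustering and de-noising.** Snippets are clustered in
   blocks of 1000 consecutive events by superparamagnetic clustering (SPC)
   over temperatures 0–0.15 in steps of 0.01; the resulting cluster tree is
   collapsed into a partition by a loss-compression rule; clusters with at
   least 15 members emit their mean waveform (a "centroid"). Unassigned
   snippets are pooled, kept in time order, and re-clustered for 4 rounds
   ("scales"), so slow-firing units that cannot reach 15 spikes per block at
   scale 1 are recovered once faster units have been removed. On realistic
   simulations this assigns ≈ 98% of snippets and compresses the data
   roughly 100-fold.
3. **Step 2 — segmentation fusion.** Centroids are pooled into blocks of
   1000 and an SPC tree (temperatures 0–0.10) is built per block. Blocks of
   10 consecutive trees, overlapping by 5, define binary linear programs:
   select tree nodes (weight = node quality) and links between nodes of
   adjacent trees (weight = waveform similarity − 0.02) subject to at most
   one node per root-to-leaf path, and at most one chosen incoming/outgoing
   link per chosen node. Links selected by *every* program covering their
   tree pair are chained into time-extended sequences — the putative single
   units. Leftover centroids join the most similar chain when their
   similarity exceeds 0.02; temporally overlapping chains with a small
   translation-invariant waveform distance (alignment duplicates of one
   unit) are merged, smallest distance first.
4. **Chain post-processing.** Chains are not linked across recording gaps or
   abrupt waveform changes, so an automated proposal stage scores every
   ordered chain pair separated by a gap: Pearson correlation of terminal
   (last/first hour) mean waveforms and of log-binned ISI histograms.
   Accept requires either correlation ≥ 0.9 and a gap of at most 5 h of
   recording time (24 h wall time across a recording gap). Ambiguous matches
   (one chain matching several neighbours) and chains below 100 µV mean
   amplitude are flagged for review, never auto-merged.

# Tracking timescale

The pipeline assumes waveform stationarity within a 1000-centroid block. At
event rate $r$ and $c$ centroids per 1000-spike block this spans
$(1000/r) \cdot 1000/c$ seconds: 16 s blocks with 8 centroids per block give
2000 s (33 min); the extremes are 16000 s (one centroid per block) and 242 s
(66 equal-rate units). `trackingTimescale()` computes this.

# The superparamagnetic clustering engine

SPC internals are not fixed by the algorithm's published description, so the
package implements the standard Potts-model formulation: q = 20 spin states,
mutual K-nearest-neighbour interaction graph (K = 11) augmented with the
Euclidean minimum spanning tree so the graph is connected (this guarantees a
single cluster at temperature 0), couplings
$J_{ij} = \tfrac{1}{\hat K}\exp(-d_{ij}^2 / 2a^2)$ with $a$ the mean
nearest-neighbour distance, Swendsen–Wang updates, and points joined when
their spin–spin correlation exceeds 0.5. Distances are plain Euclidean in
the raw 256-dimensional snippet space.

Two numerical choices matter:

* **Ordered start.** Each temperature starts from the all-equal spin state —
  the exact ground state at $T = 0$ — rather than a random state. Disordering
  is fast at high temperature, whereas coarsening from a random start at low
  temperature is slow (order $q \log n$ sweeps), so the ordered start removes
  the one systematic equilibration failure mode while leaving the
  high-temperature behaviour untouched.
* **Sweep count.** 50 burn-in + 250 measured sweeps per temperature.
  Swendsen–Wang decorrelates cluster configurations in a few sweeps at the
  temperatures of interest, and the pair-correlation estimate is thresholded
  at 0.5 — a coarse decision that is stable well before 250 sweeps on
  1000-point blocks. (Early exploratory runs used 500 sweeps with
  indistinguishable partitions at twice the cost.)

A deterministic agglomerative mode (single linkage with cut heights mapped
onto the temperature grid) is provided for fast tests; the default engine is
always SPC.

# The tree collapse and the units of the threshold *a*

For a leaf $L$ with parent $P$, the collapse rule compares the extra loss of
representing $L$'s points by $P$'s centroid instead of $L$'s own,
$d_P - d_L$, against a threshold. The published parameter table calls *a* a
"threshold distance … 20 µV", while the loss difference divided by the
degrees of freedom $\nu = 256$ is a squared-µV quantity. The package
resolves this dimensional mismatch by comparing the RMS per-degree-of-freedom
excess $\sqrt{(d_P - d_L)/\nu}$ (µV) against $a = 20$ µV. The alternative —
comparing $(d_P - d_L)/\nu$ to 20 directly — is untenable in practice: the
per-sample noise variance of filtered snippets is already ≈ 60 µV², so every
noise singleton would count as "well isolated", the partition would shatter,
and the Step-1 assignment fraction collapses to a few percent instead of the
intended ≈ 98%. With the RMS reading, a singleton noise snippet sits at
≈ σ ≈ 8 µV (merged), while a genuine 15-spike cluster 150 µV from its parent
sits at ≈ 36 µV (kept) — the intended behaviour. Note $\sqrt{(d_P-d_L)/\nu} =
\sqrt{N}\,\lVert l - p\rVert/\sqrt{\nu}$, so the rule is a per-dof distance
between centroids scaled by cluster size.

# Exact fusion solver

No mixed-integer solver is assumed. The fusion program has special
structure: the path-exclusivity constraints make the feasible node selections
of each tree exactly its *antichains*, and links only join adjacent trees, so
conditioned on per-tree selections the objective decomposes along a chain.
The solver therefore

1. prunes dominated nodes (a node whose single child has identical
   membership is strictly dominated by the deeper copy: same links, same
   exclusions, higher quality),
2. enumerates antichains per tree,
3. computes exact max-weight bipartite matchings between antichain pairs of
   adjacent trees (bitmask dynamic programming over the smaller side), and
4. runs dynamic programming over trees.

This is globally optimal and is verified against exhaustive enumeration in
the test suite. When the antichain count exceeds `maxAntichains` (default
4000 per tree) or the total matching work exceeds `maxExactWork`, the solver
falls back to greedy matching by descending link weight under all
constraints, with a warning that optimality is no longer guaranteed — the
same fallback contract a timed-out branch-and-bound would use. Ties are
broken deterministically by enumeration order.

# Link-weight normalisation

Link similarity is $\theta = 1/(1 + e^{(d-k)/s})$ with $s = 0.005$ and
$k = 0.03$, which presumes distances $d \lesssim 0.1$ — not raw µV
distances (typically tens to hundreds). The published description does not
state the normalisation. The package calibrates it per fusion run: raw
distances are scaled so that the *median nearest-neighbour distance between
leaf-node mean waveforms of adjacent trees* — the typical step between
successive local clusters of one unit — maps to $k$, the sigmoid's
half-similarity distance. Typical same-unit steps are then linkable
($\theta \approx 0.5$ and above), while links beyond ≈ 1.8 typical steps
fall under the 0.02 threshold; on realistic simulations the nearest
*cross-unit* centroid pairs sit at 2–4 typical steps, safely excluded. A
looser calibration (typical step at $k/2$) was tried first and rejected: it
left nearest cross-unit links at $\theta \approx 0.6$ and set the chain-merge
cutoff above the distance between distinct similar-amplitude units, merging
them. A fixed scale can be
supplied via `fusionParams(distScale = ...)`. The same normalised scale sets
the translation-invariant chain-merge cutoff (distance at which
$\theta = 0.5$, i.e. $d_{raw} \le k/\text{scale}$, over shifts of ±8
samples).

# The synthetic recording generator

`renderSyntheticRecording()` emulates long-term drifting tetrode data with
full ground truth:

* **Templates.** Parametric biphasic/triphasic difference-of-Gaussian shapes
  (narrow ones tagged interneurons, 20% of units), built at 10× the
  acquisition rate so each spike can be rendered at its 1/300000 s-precision
  time; the up/down-sampling emulates acquisition alignment jitter. The
  dominant channel has unit peak at the alignment sample; the other three
  channels attenuate to uniform(0.15, 0.6) of it. The steep falloff matters:
  with only 4 recorded channels the common-median reference subtracts the
  *median channel weight* of the spike itself, whereas in a many-tetrode
  array the median is insensitive to any one unit; flat channel profiles
  would make the 4-channel front end unrealistically destructive.
* **Firing.** Refractory Poisson trains (dead-time model: ISI = 1.5 ms +
  exponential, realised rate $r/(1 + r\,\tau)$); rates log-uniform over
  0.03–40 Hz, interneurons drawn from the upper part (2–40 Hz), spanning the
  ~3 orders of magnitude seen in cortex and striatum.
* **Amplitude drift.** A bounded geometric random walk evaluated at spike
  times: over a lag $\Delta t$ the walk multiplies by
  $\exp(\sqrt{\beta \Delta t}\,\varepsilon)$ and is clipped to
  $[b_{min}, b_{max}]$; each emitted spike carries independent
  signal-dependent variability $(1 + \alpha \varepsilon')$. Defaults
  $\alpha = 0.1$, $\beta = 10^{-6}\,s^{-1}$, $b_{min} = 75$ µV; $b_{max}$ is
  drawn per electrode from an exponential density (rate 0.005 µV⁻¹)
  truncated to 150–400 µV. The walk and the per-spike factor use independent
  normal draws.
* **Background and noise.** 40 background units per tetrode at 0.5 Hz each
  (20 Hz pooled), amplitudes Gaussian (mean 50, SD 25 µV, truncated at 0);
  baseline noise is Gaussian, shaped to the 300–7500 Hz band and scaled to a
  7.6 µV MAD. Overlapping spikes add linearly. Identical configuration and
  seed give bit-identical recordings.

**What the generator does not emulate:** electrode micro-drive turns and
discrete amplitude jumps, LFP content, non-Poisson firing (bursting,
oscillatory phase locking), waveform *shape* change during drift (only
amplitude drifts), and electrode-to-electrode noise correlation. Passing
tests on these simulations therefore demonstrate correct drift tracking
under smooth amplitude drift with stationary spike shapes, not performance
on every pathology of real recordings.

# Detection thresholds and the MAD

The detector's recommended threshold is 7 × the measured MAD of the filtered
recording (≈ 50 µV at the reference noise level 7.6 µV). The MAD is
estimated *per channel on the filtered, unreferenced signal*: with only four
channels, the median carries a share of both noise and spikes, and the
referenced amplitude distribution is heavier-tailed relative to its own MAD —
thresholding at 7 × the referenced MAD lands at ≈ 4.3σ and floods the
detector with noise events (~100 Hz on noise-only simulations), while the
unreferenced MAD reproduces the intended ≈ 4.7σ operating point (noise-only
false-event rate ≈ 1 Hz). Detection itself always runs on the referenced
signal. A fixed µV threshold (`detectThreshold = 50`) is the default for
real recordings; the MAD multiple is `thresholdMadMultiple`.

# Validation machinery

* `matchSpikeTrains()` performs greedy nearest-neighbour one-to-one matching
  within ±1 ms (configurable) and reports (FP + FN) / ground-truth count.
* `beerErrorRate()` computes the best ellipsoidal error rate: per unit, an
  SVM with a quadratic (polynomial degree-2) boundary on the top-3 PCA
  projections per channel (12 features), cost ratios swept over two orders
  of magnitude (10 log-spaced values), minimum test error over the sweep.
  Sorted-vs-truth unit assignment (not fixed by the published description):
  each ground-truth unit is assigned the chain minimising its error.
* `intracellularSpikeTimes()` extracts ground truth from paired
  intracellular traces (250 Hz third-order Butterworth high-pass, peaks
  above 4 robust SDs).

# Quality and stability metrics

Per-unit, per-hour isolation distance and L-ratio on the standard 16-feature
space (per channel: peak, energy, first two PCs of the hour's spikes), ISI
violation fraction (< 2 ms), and SNR (mean amplitude / (MAD × 1.4826), max
over channels). Downstream screening conventionally keeps units with
isolation distance ≥ 25, L-ratio ≤ 0.3 and ISI violations ≤ 1%; these
thresholds are applied by callers, not baked into the metric functions.
Long-term stability uses firing-rate similarity
$1 - 2|FR_i - FR_j|/(FR_i + FR_j)$ (1 = identical, −1 = one rate zero),
Pearson correlations of 50-bin log-spaced ISI histograms (1 ms–1000 s) and of
±100 ms cross-correlograms (1 ms bins, 3 ms boxcar, ±400 ms-jitter null,
two consecutive bins above 3 shuffled SDs for significance, evaluable from
5000 spikes), and a per-unit stability index: the OLS slope of similarity
versus day lag, with "stable" meaning slope ≥ −0.025/day and p ≥ 0.05.
Cell types are split by k-means (k = 2) on peak-normalised waveforms plus
log firing rate, with deterministic rate-ordered initial centers; the
higher-rate cluster is labelled fast-spiking.

# Problem sizes used in the test suite

The packaged tests exercise the full pipeline at sizes chosen to be
representative yet tractable on a single core: two one-hour single-tetrode
simulations (drifting, β = 10⁻⁶ s⁻¹, and stationary, β = 0) with 8 units on
a fixed log-spaced firing-rate ladder from 0.05 to 20 Hz (the ~3 orders of
magnitude seen in cortex and striatum; a fixed ladder keeps the event load
deterministic) plus the 20 Hz multi-unit background — roughly 10⁵ detected
events per arm. Because an hour yields only ~10³ centroids, the fusion
block is scaled to 100 centroids per tree so the program spans ~10 trees,
the windowed program size the method is designed around (the production
configuration assumes ≥ 10⁶ spikes, i.e. ~10 trees of 1000 centroids).
BEER is trained and tested on 5000-snippet subsets (the classifier's error
stabilises well below that). The oracles are 100-instance randomized
comparisons for the exact fusion solver and the tree collapse, plus
closed-form Monte-Carlo checks for the statistical estimators. End-to-end
error rates are computed on the universe of detected snippets (labelled by
±1 ms matching against ground truth), which puts the chain-based sorter and
the BEER classifier on the same footing; spikes lost to detector dead time
(~2 ms after each event) affect neither denominator. Note what these scaled
conditions imply: units at the very bottom of the rate ladder contribute
about one centroid per fusion tree and depend on the merge stages rather
than on links, and units whose amplitude sits near the detection threshold
(SNR ≲ 10 through the 4-channel front end) are only partially detected —
regimes where a supervised quadratic classifier retains an intrinsic edge
over any unsupervised sorter.

# Known limitations

* The fusion solver's exact mode is bounded by antichain enumeration; very
  bushy centroid trees fall back to the greedy heuristic (with a warning).
  On well-separated units the greedy solution almost always coincides with
  the optimum on the links that matter.
* Chains require at least two fusion trees (2000 centroids ≈ 200,000
  detected events at the default block size); shorter recordings should
  lower `centroidsPerBlock`, at the cost of a shorter tracking memory.
* Manual splitting of rare mis-sorted chains (multiple units in one chain)
  is out of scope; the proposal table flags candidates but the package never
  splits automatically.
* The 4-channel common-median reference removes a median-weight share of
  every spike; arrays with many channels should reference across all of
  them (the reader accepts any channel count).
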