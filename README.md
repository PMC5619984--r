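# fastsort

Unsupervised spike sorting for continuous, long-term tetrode recordings in
which spike waveforms drift. Chronic extracellular recordings run for days to
months; electrode drift slowly changes each unit's spike amplitude, so
sorters that cluster a static feature space lose or merge units as drift
accumulates. `fastsort` implements the FAST approach — cluster locally in
time, then link local clusters through time:

1. **Spike identification** — zero-phase elliptic band-pass (300–7500 Hz),
   common-median referencing, threshold-crossing detection (7 × MAD ≈ 50 µV)
   with hysteretic re-arm, 64-sample × 4-channel snippets (256-D vectors).
2. **Step 1: local clustering** — superparamagnetic clustering (SPC) of
   1000-spike blocks over temperatures T = 0.01·i, i = 0…15, cluster-tree
   collapse by a loss-compression rule (threshold *a* = 20 µV per degree of
   freedom, RMS scale), centroids from clusters of ≥ 15 spikes, iterated over
   4 temporal scales so slow units are recovered after fast ones are removed.
   Output: de-noised mean waveforms, ~100× fewer than the input spikes.
3. **Step 2: segmentation fusion** — SPC trees over 1000-centroid blocks;
   overlapping binary linear programs (10 trees per program, 5 overlap)
   select tree nodes (weight = node quality N(0)/ΣN(m) along the
   largest-child path) and links between adjacent trees (weight = sigmoid
   similarity θ = 1/(1+e^{(d−k)/s}), s = 0.005, k = 0.03, minus a 0.02
   threshold), subject to one-node-per-root-leaf-path and at most one chosen
   link in/out per node. Links chosen by every covering program are chained
   into drift-tracked single units; stragglers attach above θ = 0.02;
   alignment-duplicate chains merge by translation-invariant distance.
4. **Chain merge proposals** — across recording gaps, chains merge when
   terminal waveform or ISI-histogram correlation is ≥ 0.9 and the gap is
   ≤ 5 h of recording (≤ 24 h across an acquisition gap); ambiguous or
   low-amplitude (< 100 µV) matches are flagged, never auto-merged.

The package also provides the synthetic drifting-recording generator used
for validation (bounded geometric random-walk amplitude drift
A(t+Δt) = A(t)·exp(√(βΔt)·ε) clipped to [b_min, b_max], signal-dependent
variability (1+αε′), refractory Poisson spike trains, 20 Hz multi-unit
background, band-limited noise), ground-truth evaluation (greedy ±1 ms
spike matching; the BEER optimal-quadratic-classifier baseline), and
cluster-quality / cell-type / correlogram / long-term stability metrics.

See the methods vignette (`vignettes/fastsort-methods.Rmd`) for the models,
parameter meanings and design decisions.

## Worked example

Simulate one hour of a stationary tetrode — 8 units on a log-spaced rate
ladder (0.05–20 Hz) over a 20 Hz multi-unit background — detect and sort it,
and score every ground-truth unit against its best-matching chain:

```r
library(fastsort)

rates <- exp(seq(log(0.05), log(20), length.out = 8))
sim <- renderSyntheticRecording(3600, seed = 42, rates = rates,
                                model = driftModel(beta = 0))
sn  <- snippetRecording(sim$recording,
                        detectionParams(thresholdMadMultiple = 7))[[1]]
sn
#> SnippetSet: 97232 snippet(s), tetrode 1, 4 x 64 samples @ 30000 Hz

res <- sortSnippets(sn, step2 = fusionParams(centroidsPerBlock = 100L),
                    seed = 43)
res$centroids
#> CentroidSet: 829 centroid(s) over 4 scale(s), 96988 member spike(s), 244 unassigned
res$chains
#> ChainSet: 130 chain(s) over 829 centroid(s), 0 unassigned
#>   chain lengths: median 1, max 97 centroids

for (u in seq_len(nrow(sim$truth@units))) {
  errs <- vapply(res$spikeTimes, function(tt)
    matchSpikeTrains(tt, sim$truth@spikeTimes[[u]])$errorRate, 0)
  cat(sprintf("unit %d (SNR %4.1f, %5.2f Hz): error %.3f\n",
              u, sim$truth@units$snr[u], sim$truth@units$rate[u], min(errs)))
}
#> unit 1 (SNR 16.3,  0.05 Hz): error 0.525
#> unit 2 (SNR 20.4,  0.12 Hz): error 0.461
#> unit 3 (SNR  9.6,  0.28 Hz): error 1.004
#> unit 4 (SNR 24.4,  0.65 Hz): error 0.097
#> unit 5 (SNR 21.2,  1.53 Hz): error 0.094
#> unit 6 (SNR  9.1,  3.61 Hz): error 0.257
#> unit 7 (SNR  8.5,  8.50 Hz): error 1.000
#> unit 8 (SNR 14.4, 20.00 Hz): error 0.134
```

The error is (false positives + false negatives) / (ground-truth spikes),
against the full ground-truth trains. The numbers tell the method's honest
story: units the detector sees well (SNR ≳ 13 here) come out at 9–13%
error — dominated by detector dead-time collisions, not mis-sorting (chain
purities are 0.95–1.00); units whose amplitude sits near the detection
threshold through the 4-channel front end (SNR ≈ 8–10: units 3 and 7) are
mostly lost by the detector itself; and ultra-slow units (0.05–0.12 Hz)
contribute about one de-noised centroid per fusion tree, so their recovery
leans on the merge stages and stays partial at this one-hour scale (the
production configuration assumes multi-hour recordings and ≥ 10⁶ spikes).
Step 1 assigned 96988 / 97232 = 99.7% of snippets, a 117-fold compression.
The run takes ≈ 2 minutes on one core. The many length-1 chains are
single-node fragments of the sparse units and of the multi-unit background,
kept so the merge stages (and a human reviewer) can act on them.

`trackingTimescale(1000/16, 8)` reproduces the drift-correction arithmetic:
a 62.5 Hz event rate with 8 centroids per 1000-spike block gives a 2000 s
(33 min) tracking timescale.

A command-line front end wrapping the same functions (subcommands
`simulate`, `snippet`, `sort`, `validate`, `metrics`, with a flat key=value
config file and per-stage manifests) is installed at
`inst/cli/fastsort.R`:

```sh
Rscript $(Rscript -e 'cat(system.file("cli/fastsort.R", package="fastsort"))') \
    simulate --config run.cfg --out runs/demo
```

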