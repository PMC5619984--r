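# End-to-end drifting-recording evaluation shared by the acceptance tests.
# The two one-hour simulations (drifting and stationary) are expensive, so
# they are computed lazily, cached for the whole test run, and reduced to
# compact summaries (feature matrix, labels, chain membership) so that both
# runs fit in memory together.

.e2e_cache <- new.env(parent = emptyenv())

e2e_run <- function(beta, seed = 42, duration = 3600) {
  key <- paste0("b", beta)
  if (!is.null(.e2e_cache[[key]])) return(.e2e_cache[[key]])
  # 8 units with a fixed log-spaced rate ladder spanning the ~3 orders of
  # magnitude seen in cortex/striatum; deterministic load across seeds
  rates <- exp(seq(log(0.05), log(20), length.out = 8))
  sim <- renderSyntheticRecording(duration, seed = seed, rates = rates,
                                  model = driftModel(beta = beta))
  sn <- snippetRecording(sim$recording,
                         detectionParams(thresholdMadMultiple = 7))[[1]]
  if (!is.null(sim$recording@path)) unlink(sim$recording@path)
  # centroid blocks scaled with the recording so the fusion program spans
  # ~10 trees, the windowed program size the algorithm is designed around
  res <- sortSnippets(sn, step2 = fusionParams(centroidsPerBlock = 100L),
                      seed = seed + 1)
  # label every detected snippet with its ground-truth unit (1 ms tolerance)
  snt <- peakTimes(sn) / sn@sampleRate
  labels <- rep(0L, nSpikes(sn))
  for (u in seq_len(nrow(sim$truth@units))) {
    mt <- matchSpikeTrains(snt, sim$truth@spikeTimes[[u]])
    labels[mt$pairs[, "sorted"]] <- u
  }
  # BEER feature matrix (12-D), so the 256-D waveforms can be dropped
  feats <- fastsort:::channel_pca_features(waveforms(sn), sn@nChannels)
  chain_snips <- lapply(res$chains@chains, function(ci)
    sort(unlist(res$centroids@members[ci], use.names = FALSE)))
  out <- list(truth = sim$truth, features = feats, labels = labels,
              nSnippets = nSpikes(sn), chainSnips = chain_snips)
  .e2e_cache[[key]] <- out
  out
}

# FAST per-unit error on the detected-snippet universe: for each truth unit,
# the best chain's (FP + FN) / unit snippet count
fast_unit_errors <- function(run) {
  units <- sort(setdiff(unique(run$labels), 0))
  vapply(units, function(u) {
    tu <- which(run$labels == u)
    if (!length(run$chainSnips)) return(2)
    errs <- vapply(run$chainSnips, function(p) {
      (length(setdiff(p, tu)) + length(setdiff(tu, p))) / length(tu)
    }, 0)
    min(errs)
  }, 0)
}
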