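#' Propose chain merges across discontinuities
#'
#' The fully automatic steps do not link chains across recording gaps, abrupt
#' waveform changes, or spells of sub-detection amplitude. This stage scores
#' every ordered chain pair separated by a time gap and proposes merges based
#' on end-to-beginning similarity: the Pearson correlation between mean spike
#' waveforms and between inter-spike-interval histograms, both computed over
#' each chain's terminal window (default 1 h). A proposal is accepted when
#' either correlation is at least \code{corrThreshold} (0.9) and the gap is at
#' most \code{maxGapRecording} hours of recording time, or up to
#' \code{maxGapWall} hours of wall time when a recording gap intervenes.
#' Chains whose mean amplitude is below \code{ampFlag} uV, or that match
#' multiple neighbours at or above the correlation threshold, are flagged for
#' review and never auto-merged. Chains with fewer than \code{minIsiSpikes}
#' spikes in the window skip the ISI criterion (the waveform criterion alone
#' decides, marked low-confidence).
#'
#' @param chainSet a \code{\linkS4class{ChainSet}}.
#' @param centroids the \code{CentroidSet} the chains index.
#' @param snippets the source \code{SnippetSet}.
#' @param recordingGaps optional matrix with columns \code{start}, \code{end}
#'   (seconds of wall time) marking spans with no recorded data.
#' @param windowHours terminal-statistics window, hours.
#' @param corrThreshold similarity threshold for acceptance.
#' @param maxGapRecording,maxGapWall gap limits, hours.
#' @param minIsiSpikes minimum spikes for the ISI criterion.
#' @param ampFlag amplitude (uV) below which chains are only flagged.
#' @return data.frame with one row per candidate pair: chain indices, gaps
#'   (hours), correlations, \code{decision} (accept/reject/flag) and
#'   \code{lowConfidence}. Decisions are a pure function of the pair table,
#'   so they do not depend on chain enumeration order.
#' @export
proposeChainMerges <- function(chainSet, centroids, snippets,
                               recordingGaps = NULL, windowHours = 1,
                               corrThreshold = 0.9, maxGapRecording = 5,
                               maxGapWall = 24, minIsiSpikes = 100,
                               ampFlag = 100) {
  fs <- snippets@sampleRate
  times <- chainSpikeTimes(chainSet, centroids, snippets)
  nch <- length(times)
  empty <- data.frame(chainA = integer(), chainB = integer(),
                      gapWall = numeric(), gapRecording = numeric(),
                      waveformCorr = numeric(), isiCorr = numeric(),
                      decision = character(), lowConfidence = logical())
  if (nch < 2L) return(empty)
  wf <- waveforms(centroids)
  cnt <- centroids@counts
  ctimes <- centroids@medianTimes / fs
  win <- windowHours * 3600
  term_stats <- function(ci, at_end) {
    tt <- times[[ci]]
    window <- if (at_end) c(max(tt) - win, max(tt)) else c(min(tt), min(tt) + win)
    cent <- chainSet@chains[[ci]]
    use <- cent[ctimes[cent] >= window[1] & ctimes[cent] <= window[2]]
    if (!length(use)) use <- cent
    w <- cnt[use]
    mw <- colSums(wf[use, , drop = FALSE] * w) / sum(w)
    st <- tt[tt >= window[1] & tt <= window[2]]
    list(wf = mw, isi = isiHistogram(st), n = length(st))
  }
  spans <- t(vapply(times, range, numeric(2)))
  mean_amp <- vapply(seq_len(nch), function(ci) {
    cent <- chainSet@chains[[ci]]
    w <- cnt[cent]
    max(abs(colSums(wf[cent, , drop = FALSE] * w) / sum(w)))
  }, 0)
  gap_in <- function(t0, t1) {
    if (is.null(recordingGaps) || !nrow(recordingGaps)) return(0)
    lo <- pmax(recordingGaps[, 1], t0)
    hi <- pmin(recordingGaps[, 2], t1)
    sum(pmax(hi - lo, 0))
  }
  ends <- lapply(seq_len(nch), term_stats, at_end = TRUE)
  starts <- lapply(seq_len(nch), term_stats, at_end = FALSE)
  rows <- list()
  for (a in seq_len(nch)) for (b in seq_len(nch)) {
    if (a == b) next
    gap_wall <- spans[b, 1] - spans[a, 2]
    if (gap_wall < 0) next  # overlapping chains belong to the merge stage
    g <- gap_in(spans[a, 2], spans[b, 1])
    gap_rec <- max(0, gap_wall - g)
    ea <- ends[[a]]
    sb <- starts[[b]]
    wf_corr <- suppressWarnings(stats::cor(ea$wf, sb$wf))
    low <- ea$n < minIsiSpikes || sb$n < minIsiSpikes
    isi_corr <- if (low) NA_real_ else
      suppressWarnings(stats::cor(ea$isi, sb$isi))
    gap_ok <- gap_rec / 3600 <= maxGapRecording ||
      (g > 0 && gap_wall / 3600 <= maxGapWall)
    sim_ok <- isTRUE(wf_corr >= corrThreshold) ||
      isTRUE(isi_corr >= corrThreshold)
    rows[[length(rows) + 1L]] <- data.frame(
      chainA = a, chainB = b, gapWall = gap_wall / 3600,
      gapRecording = gap_rec / 3600,
      waveformCorr = wf_corr, isiCorr = isi_corr,
      decision = if (gap_ok && sim_ok) "accept" else "reject",
      lowConfidence = low)
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  # ambiguity and low-amplitude rules: flag, never auto-merge. A serial run
  # of fragments (each continuing the previous, disjoint in time) is not
  # ambiguous even though every fragment matches all later ones; ambiguity
  # means two candidate continuations that overlap each other in time.
  amp_ok <- mean_amp[out$chainA] >= ampFlag & mean_amp[out$chainB] >= ampFlag
  hi <- out[out$decision == "accept" & amp_ok, , drop = FALSE]
  parallel <- function(members) {
    if (length(members) < 2) return(FALSE)
    sp <- spans[members, , drop = FALSE]
    ord <- order(sp[, 1])
    any(sp[ord, 1][-1] <= cummax(sp[ord, 2])[-length(members)])
  }
  amb <- rep(FALSE, nrow(out))
  for (a in unique(hi$chainA)) {
    succ <- hi$chainB[hi$chainA == a]
    if (parallel(succ)) amb <- amb | (out$chainA == a & out$chainB %in% succ)
  }
  for (b in unique(hi$chainB)) {
    pred <- hi$chainA[hi$chainB == b]
    if (parallel(pred)) amb <- amb | (out$chainB == b & out$chainA %in% pred)
  }
  flag <- out$decision == "accept" & (amb | !amp_ok)
  out$decision[flag] <- "flag"
  out
}

#' Apply accepted merge proposals
#'
#' Unions the chains of all \code{accept} rows (transitively). Merging never
#' duplicates snippets: chains are disjoint centroid sets, so their union is
#' again a valid chain.
#'
#' @param chainSet a \code{ChainSet}.
#' @param proposals the table from \code{\link{proposeChainMerges}}.
#' @return The merged \code{ChainSet}.
#' @export
applyChainMerges <- function(chainSet, proposals) {
  acc <- proposals[proposals$decision == "accept", , drop = FALSE]
  n <- length(chainSet@chains)
  if (!nrow(acc) || n < 2L) return(chainSet)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (r in seq_len(nrow(acc))) {
    i <- find(acc$chainA[r]); j <- find(acc$chainB[r])
    if (i != j) parent[max(i, j)] <- min(i, j)
  }
  roots <- vapply(seq_len(n), find, 0L)
  merged <- lapply(unique(roots), function(r)
    sort(unlist(chainSet@chains[roots == r], use.names = FALSE)))
  new("ChainSet", chains = merged, unassigned = chainSet@unassigned,
      nCentroids = chainSet@nCentroids,
      log = c(chainSet@log, list(mergesApplied = nrow(acc))))
}
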