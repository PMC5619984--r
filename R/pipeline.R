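#' Sort a snippet store into single-unit chains
#'
#' Runs the two automatic processing steps on one tetrode's snippets:
#' multi-scale local clustering into de-noised centroids (Step 1), then
#' segmentation fusion of centroid cluster trees into drift-tracked chains
#' (Step 2), followed by the automated chain merge-proposal stage across
#' temporal discontinuities.
#'
#' @param snippets a \code{SnippetSet}.
#' @param step1 a \code{CollapseParams}.
#' @param step2 a \code{FusionParams}.
#' @param seed integer seed.
#' @param method clustering engine (\code{"spc"} or \code{"agglomerative"}).
#' @param autoMerge apply accepted cross-gap merge proposals.
#' @param recordingGaps optional gap table for the merge proposals.
#' @param verbose print stage progress.
#' @return list with \code{centroids} (\code{CentroidSet}), \code{chains}
#'   (\code{ChainSet}), \code{proposals} (merge-proposal table) and
#'   \code{spikeTimes} (per-chain spike times, s).
#' @export
sortSnippets <- function(snippets, step1 = collapseParams(),
                         step2 = fusionParams(), seed = NULL,
                         method = "spc", autoMerge = TRUE,
                         recordingGaps = NULL, verbose = FALSE) {
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  if (verbose) message(sprintf("step 1: clustering %d snippet(s)",
                               nSpikes(snippets)))
  centroids <- multiscaleCluster(snippets, step1, method = method,
                                 verbose = verbose)
  if (verbose) message(sprintf("step 2: fusing %d centroid(s)",
                               nCentroids(centroids)))
  pt <- peakTimes(snippets)
  extents <- t(vapply(centroids@members, function(m) range(pt[m]),
                      numeric(2)))
  chainset <- fuseCentroids(centroids, step2, method = method,
                            extents = extents, verbose = verbose)
  proposals <- proposeChainMerges(chainset, centroids, snippets,
                                  recordingGaps = recordingGaps)
  if (autoMerge && nrow(proposals))
    chainset <- applyChainMerges(chainset, proposals)
  list(centroids = centroids, chains = chainset, proposals = proposals,
       spikeTimes = chainSpikeTimes(chainset, centroids, snippets))
}

#' Sort a raw recording end to end
#'
#' Convenience wrapper: snippets every tetrode of a raw recording and sorts
#' each tetrode with \code{\link{sortSnippets}}.
#'
#' @param rec a \code{RawRecording}.
#' @param detection a \code{DetectionParams}.
#' @param ... passed to \code{\link{sortSnippets}}.
#' @return named list (one element per tetrode) of \code{sortSnippets}
#'   results, each with the tetrode's \code{snippets} added.
#' @export
sortRecording <- function(rec, detection = detectionParams(), ...) {
  snips <- snippetRecording(rec, detection)
  out <- lapply(names(snips), function(t) {
    res <- sortSnippets(snips[[t]], ...)
    res$snippets <- snips[[t]]
    res
  })
  names(out) <- names(snips)
  out
}
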