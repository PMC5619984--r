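#' Accessors for fastsort containers
#'
#' Small accessor generics: \code{nSpikes} counts events in a
#' \code{SnippetSet}, \code{peakTimes} returns their global peak sample
#' indices, \code{waveforms} the waveform matrix (events or centroids in rows,
#' channels concatenated), \code{chains} the list of centroid-index chains,
#' and \code{nCentroids} the number of centroids.
#'
#' @param x a fastsort object.
#' @return See each method.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nSpikes", function(x) standardGeneric("nSpikes"))
#' @rdname accessors
#' @export
setGeneric("peakTimes", function(x) standardGeneric("peakTimes"))
#' @rdname accessors
#' @export
setGeneric("waveforms", function(x) standardGeneric("waveforms"))
#' @rdname accessors
#' @export
setGeneric("chains", function(x) standardGeneric("chains"))
#' @rdname accessors
#' @export
setGeneric("nCentroids", function(x) standardGeneric("nCentroids"))

#' @rdname accessors
#' @export
setMethod("nSpikes", "SnippetSet", function(x) length(x@peakTimes))
#' @rdname accessors
#' @export
setMethod("peakTimes", "SnippetSet", function(x) x@peakTimes)
#' @rdname accessors
#' @export
setMethod("waveforms", "SnippetSet", function(x) x@waveforms)
#' @rdname accessors
#' @export
setMethod("waveforms", "CentroidSet", function(x) x@waveforms)
#' @rdname accessors
#' @export
setMethod("nCentroids", "CentroidSet", function(x) nrow(x@waveforms))
#' @rdname accessors
#' @export
setMethod("chains", "ChainSet", function(x) x@chains)
#' @rdname accessors
#' @export
setMethod("nCentroids", "ChainSet", function(x) x@nCentroids)

setMethod("show", "RawRecording", function(object) {
  cat(sprintf("RawRecording: %d channel(s), %.0f samples @ %g Hz (%s)\n",
              object@nChannels, object@nSamples, object@sampleRate,
              if (is.null(object@path)) "in memory" else object@path))
  cat(sprintf("  %d tetrode(s), %d segment(s), %.4g uV/bit\n",
              length(object@tetrodeMap), nrow(object@segments),
              object@uvPerBit))
})

setMethod("show", "SnippetSet", function(object) {
  cat(sprintf("SnippetSet: %d snippet(s), tetrode %d, %d x %d samples @ %g Hz\n",
              nSpikes(object), object@tetrode, object@nChannels,
              object@samplesPerSpike, object@sampleRate))
})

setMethod("show", "SpcTree", function(object) {
  cat(sprintf("SpcTree: %d point(s), %d node(s), depth %d\n",
              object@nPoints, length(object@members), max(object@depth)))
})

setMethod("show", "CentroidSet", function(object) {
  m <- nCentroids(object)
  cat(sprintf("CentroidSet: %d centroid(s) over %d scale(s), %d member spike(s), %d unassigned\n",
              m, if (m) max(object@scale) else 0L,
              sum(object@counts), length(object@unassigned)))
})

setMethod("show", "ChainSet", function(object) {
  cl <- lengths(object@chains)
  cat(sprintf("ChainSet: %d chain(s) over %d centroid(s), %d unassigned\n",
              length(cl), object@nCentroids, length(object@unassigned)))
  if (length(cl))
    cat(sprintf("  chain lengths: median %g, max %g centroids\n",
                stats::median(cl), max(cl)))
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %d unit(s) on %d tetrode(s), %d background event(s)\n",
              nrow(object@units), length(unique(object@units$tetrode)),
              length(object@background$times)))
})
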