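#' @import methods
NULL

setClassUnion("characterOrNULL", c("character", "NULL"))

#' Spike detection and snippeting parameters
#'
#' Parameters controlling band-pass filtering, common-median referencing and
#' threshold-crossing spike detection. Defaults follow the recommended values
#' for 30 kHz tetrode recordings: 15 s processing blocks with 100 ms padding,
#' a 300--7500 Hz fourth-order elliptic band-pass applied forward and reverse
#' (zero phase), a 50 uV detection threshold (about 7x the median absolute
#' deviation of a typical recording; set \code{thresholdMadMultiple} to use an
#' explicit MAD multiple instead), a return threshold of 3x MAD that must hold
#' for 8 consecutive samples before the detector re-arms, and 64-sample
#' snippets (31 before the peak, the peak, 32 after).
#'
#' @slot blockLen numeric(1), processing block length in seconds.
#' @slot pad numeric(1), filter padding on each block end, seconds.
#' @slot detectThreshold numeric(1), detection threshold in uV (ignored when
#'   \code{thresholdMadMultiple} is finite).
#' @slot thresholdMadMultiple numeric(1), detection threshold as a multiple of
#'   the per-block MAD; \code{NA} (default) uses \code{detectThreshold}.
#' @slot returnThreshold numeric(1), re-arm threshold as a MAD multiple.
#' @slot returnSamples integer(1), consecutive sub-threshold samples to re-arm.
#' @slot band numeric(2), band-pass cut-off frequencies in Hz.
#' @slot prePeak,postPeak integer(1), snippet samples before/after the peak.
#' @slot filterRipple numeric(1), elliptic passband ripple (dB).
#' @slot filterAttenuation numeric(1), elliptic stopband attenuation (dB).
#' @exportClass DetectionParams
setClass("DetectionParams",
  representation(
    blockLen = "numeric", pad = "numeric",
    detectThreshold = "numeric", thresholdMadMultiple = "numeric",
    returnThreshold = "numeric", returnSamples = "integer",
    band = "numeric", prePeak = "integer", postPeak = "integer",
    filterRipple = "numeric", filterAttenuation = "numeric"
  ),
  prototype(
    blockLen = 15, pad = 0.1,
    detectThreshold = 50, thresholdMadMultiple = NA_real_,
    returnThreshold = 3, returnSamples = 8L,
    band = c(300, 7500), prePeak = 31L, postPeak = 32L,
    filterRipple = 0.1, filterAttenuation = 40
  ),
  validity = function(object) {
    msg <- character()
    if (object@blockLen <= 0) msg <- c(msg, "blockLen must be positive")
    if (object@pad < 0) msg <- c(msg, "pad must be non-negative")
    if (length(object@band) != 2L || any(object@band <= 0) ||
        diff(object@band) <= 0)
      msg <- c(msg, "band must be increasing positive frequencies")
    if (object@prePeak < 1L || object@postPeak < 1L)
      msg <- c(msg, "prePeak and postPeak must be >= 1")
    if (object@returnSamples < 1L) msg <- c(msg, "returnSamples must be >= 1")
    if (is.finite(object@thresholdMadMultiple) &&
        object@returnThreshold >= object@thresholdMadMultiple)
      msg <- c(msg, "returnThreshold must be below the detection threshold")
    if (length(msg)) msg else TRUE
  }
)

#' @rdname DetectionParams-class
#' @param ... slot values overriding the defaults.
#' @return A \code{DetectionParams} object.
#' @export
detectionParams <- function(...) new("DetectionParams", ...)

#' Raw multichannel extracellular recording
#'
#' Container for a raw recording in ADC counts, either held in memory
#' (\code{samples} matrix, channels x time) or file-backed (flat binary
#' little-endian int16, channel-interleaved: all channels of sample 1, then
#' all channels of sample 2, ...). Segments mark contiguous acquisition spans;
#' gaps between segments are periods with no recorded data.
#'
#' @slot samples integer matrix [channels x time] in ADC counts (0 x 0 when
#'   file-backed).
#' @slot path character(1) path of the flat int16 file, or \code{NULL}.
#' @slot nChannels,nSamples integer/numeric recording dimensions.
#' @slot sampleRate numeric(1), Hz.
#' @slot uvPerBit numeric(1), microvolts per ADC count.
#' @slot tetrodeMap named list mapping tetrode id to 4 channel indices.
#' @slot segments numeric matrix with columns \code{start}, \code{end}
#'   (1-based inclusive sample indices), non-overlapping and ordered.
#' @exportClass RawRecording
setClass("RawRecording",
  representation(
    samples = "matrix", path = "characterOrNULL",
    nChannels = "integer", nSamples = "numeric",
    sampleRate = "numeric", uvPerBit = "numeric",
    tetrodeMap = "list", segments = "matrix"
  ),
  validity = function(object) {
    msg <- character()
    chans <- unlist(object@tetrodeMap, use.names = FALSE)
    if (anyDuplicated(chans))
      msg <- c(msg, "tetrodeMap channels must be distinct")
    if (length(chans) && (any(chans < 1) || any(chans > object@nChannels)))
      msg <- c(msg, "tetrodeMap channels out of range")
    seg <- object@segments
    if (nrow(seg)) {
      if (any(seg[, 2] < seg[, 1]))
        msg <- c(msg, "segment end before start")
      if (nrow(seg) > 1 && any(seg[-1, 1] <= seg[-nrow(seg), 2]))
        msg <- c(msg, "segments must be ordered and non-overlapping")
      if (max(seg) > object@nSamples)
        msg <- c(msg, "segment exceeds recording length")
    }
    if (is.null(object@path) && !identical(dim(object@samples),
        c(object@nChannels, as.integer(object@nSamples))))
      msg <- c(msg, "in-memory samples must be [nChannels x nSamples]")
    if (length(msg)) msg else TRUE
  }
)

#' @rdname RawRecording-class
#' @param samples integer matrix [channels x time] in ADC counts.
#' @param sampleRate sampling rate in Hz.
#' @param uvPerBit microvolts per ADC count.
#' @param tetrodeMap named list of 4-channel index vectors.
#' @param segments matrix of (start, end) sample indices; default one segment
#'   covering the whole recording.
#' @param path flat int16 file path for file-backed recordings.
#' @param nChannels,nSamples dimensions (required when file-backed).
#' @return A \code{RawRecording}.
#' @export
rawRecording <- function(samples = NULL, sampleRate = 30000, uvPerBit = 0.195,
                         tetrodeMap = NULL, segments = NULL, path = NULL,
                         nChannels = NULL, nSamples = NULL) {
  if (!is.null(samples)) {
    storage.mode(samples) <- "integer"
    nChannels <- nrow(samples)
    nSamples <- ncol(samples)
  } else {
    if (is.null(path) || is.null(nChannels) || is.null(nSamples))
      stop("file-backed recordings need path, nChannels and nSamples")
    samples <- matrix(integer(), 0, 0)
  }
  if (is.null(tetrodeMap)) {
    nt <- nChannels %/% 4L
    tetrodeMap <- lapply(seq_len(nt), function(i) ((i - 1L) * 4L) + 1:4)
    names(tetrodeMap) <- as.character(seq_len(nt))
  }
  if (is.null(segments)) segments <- cbind(start = 1, end = nSamples)
  colnames(segments) <- c("start", "end")
  new("RawRecording", samples = samples, path = path,
      nChannels = as.integer(nChannels), nSamples = as.numeric(nSamples),
      sampleRate = sampleRate, uvPerBit = uvPerBit,
      tetrodeMap = tetrodeMap, segments = segments)
}

#' Detected spike snippets for one tetrode
#'
#' Each detected event is a 64-sample, 4-channel waveform excerpt in uV
#' aligned so the across-channel absolute maximum sits at sample 32 (31
#' samples precede the peak, 32 follow). Waveforms are stored one event per
#' row, channels concatenated (channel 1 samples 1..64, channel 2 ...), so a
#' tetrode snippet is a 256-dimensional vector.
#'
#' @slot peakTimes numeric, global peak sample indices (monotone increasing).
#' @slot waveforms numeric matrix [events x (channels * samplesPerSpike)], uV.
#' @slot tetrode integer(1) tetrode id.
#' @slot nChannels,samplesPerSpike integer waveform geometry.
#' @slot sampleRate numeric(1), Hz.
#' @slot params the \code{DetectionParams} used.
#' @slot segments segment table of the source recording.
#' @slot log list of per-run counters (edge-discarded events, MAD estimates).
#' @exportClass SnippetSet
setClass("SnippetSet",
  representation(
    peakTimes = "numeric", waveforms = "matrix", tetrode = "integer",
    nChannels = "integer", samplesPerSpike = "integer",
    sampleRate = "numeric", params = "DetectionParams",
    segments = "matrix", log = "list"
  ),
  validity = function(object) {
    msg <- character()
    if (nrow(object@waveforms) != length(object@peakTimes))
      msg <- c(msg, "waveforms rows must match peakTimes length")
    if (length(object@peakTimes) > 1 && is.unsorted(object@peakTimes))
      msg <- c(msg, "peakTimes must be non-decreasing")
    if (nrow(object@waveforms) &&
        ncol(object@waveforms) != object@nChannels * object@samplesPerSpike)
      msg <- c(msg, "waveform width must equal nChannels * samplesPerSpike")
    if (length(msg)) msg else TRUE
  }
)

#' Multi-temperature cluster tree of one block of waveforms
#'
#' Hierarchy of superparamagnetic clusters across a temperature grid. The
#' root (depth 0) holds all points; nodes at depth d correspond to clusters at
#' the d-th temperature and the children of any node partition its members.
#'
#' @slot nPoints integer(1), points clustered.
#' @slot temperatures numeric, the temperature grid (first entry depth 0).
#' @slot members list of sorted integer vectors, one per node.
#' @slot depth integer, node depths (root = 0).
#' @slot parent integer, parent node index (0 for the root).
#' @slot children list of integer vectors of child node indices.
#' @exportClass SpcTree
setClass("SpcTree",
  representation(
    nPoints = "integer", temperatures = "numeric", members = "list",
    depth = "integer", parent = "integer", children = "list"
  ),
  validity = function(object) {
    msg <- character()
    nn <- length(object@members)
    if (length(object@depth) != nn || length(object@parent) != nn ||
        length(object@children) != nn)
      msg <- c(msg, "per-node slots must have equal length")
    if (nn) {
      root <- which(object@depth == 0L)
      if (length(root) != 1L || length(object@members[[root]]) != object@nPoints)
        msg <- c(msg, "exactly one root containing all points required")
      for (i in seq_len(nn)) {
        kids <- object@children[[i]]
        if (length(kids)) {
          km <- sort(unlist(object@members[kids], use.names = FALSE))
          if (!identical(km, object@members[[i]]))
            msg <- c(msg, sprintf("children of node %d do not partition it", i))
        }
      }
    }
    if (length(msg)) msg else TRUE
  }
)

#' Step-1 collapse and multi-scale clustering parameters
#'
#' @slot mergeThreshold numeric(1), loss-excess threshold `a` for recursive
#'   tree collapse: the RMS per-degree-of-freedom extra loss, in uV, above
#'   which a leaf is a distinct cluster (default 20).
#' @slot dof numeric(1), degrees of freedom nu (256 for a tetrode snippet).
#' @slot minClusterSize integer(1), minimum spikes for an emitted centroid.
#' @slot blockSize integer(1), spikes per local-clustering block.
#' @slot nScales integer(1), rounds of multi-scale clustering.
#' @slot minPartialBlock integer(1), minimum size of a trailing partial block
#'   to cluster at the current scale (smaller blocks carry to the next scale).
#' @slot minSpcSize integer(1), below this, a block is not clustered at all.
#' @slot tMax,tStep numeric(1), SPC temperature grid (0 to tMax by tStep).
#' @exportClass CollapseParams
setClass("CollapseParams",
  representation(
    mergeThreshold = "numeric", dof = "numeric", minClusterSize = "integer",
    blockSize = "integer", nScales = "integer", minPartialBlock = "integer",
    minSpcSize = "integer", tMax = "numeric", tStep = "numeric"
  ),
  prototype(
    mergeThreshold = 20, dof = 256, minClusterSize = 15L, blockSize = 1000L,
    nScales = 4L, minPartialBlock = 100L, minSpcSize = 20L,
    tMax = 0.15, tStep = 0.01
  ),
  validity = function(object) {
    msg <- character()
    if (object@mergeThreshold <= 0 || object@dof <= 0)
      msg <- c(msg, "mergeThreshold and dof must be positive")
    if (object@blockSize < object@minClusterSize)
      msg <- c(msg, "blockSize must be >= minClusterSize")
    if (object@nScales < 1L) msg <- c(msg, "nScales must be >= 1")
    if (length(msg)) msg else TRUE
  }
)

#' @rdname CollapseParams-class
#' @param ... slot values overriding the defaults.
#' @return A \code{CollapseParams} object.
#' @export
collapseParams <- function(...) new("CollapseParams", ...)

#' De-noised centroid waveforms (Step-1 output)
#'
#' Time-ordered averaged spike waveforms, each the arithmetic mean of at
#' least \code{minClusterSize} similar snippets, with back-pointers to the
#' member snippets and the multi-scale round that produced them.
#'
#' @slot waveforms numeric matrix [centroids x (channels * samples)], uV.
#' @slot medianTimes numeric, median member peak time (samples) per centroid.
#' @slot counts integer, member count per centroid.
#' @slot scale integer, multi-scale round (1-based) per centroid.
#' @slot members list of integer vectors of member snippet indices.
#' @slot unassigned integer, snippet indices never assigned to a centroid.
#' @slot nChannels,samplesPerSpike integer waveform geometry.
#' @exportClass CentroidSet
setClass("CentroidSet",
  representation(
    waveforms = "matrix", medianTimes = "numeric", counts = "integer",
    scale = "integer", members = "list", unassigned = "integer",
    nChannels = "integer", samplesPerSpike = "integer"
  ),
  validity = function(object) {
    msg <- character()
    m <- nrow(object@waveforms)
    if (length(object@medianTimes) != m || length(object@counts) != m ||
        length(object@scale) != m || length(object@members) != m)
      msg <- c(msg, "per-centroid slots must have equal length")
    if (m && !identical(object@counts, lengths(object@members)))
      msg <- c(msg, "counts must equal member lengths")
    if (m > 1 && is.unsorted(object@medianTimes))
      msg <- c(msg, "centroids must be ordered by median spike time")
    all_members <- unlist(object@members, use.names = FALSE)
    if (anyDuplicated(all_members))
      msg <- c(msg, "member sets must be disjoint across centroids")
    if (length(intersect(all_members, object@unassigned)))
      msg <- c(msg, "unassigned snippets cannot also be members")
    if (length(msg)) msg else TRUE
  }
)

#' Segmentation-fusion parameters (Step 2)
#'
#' @slot centroidsPerBlock integer(1), centroids per SPC tree (default 1000).
#' @slot treesPerIlp integer(1), cluster trees per fusion program (10).
#' @slot ilpOverlap integer(1), tree overlap between consecutive programs (5).
#' @slot sigmoidS,sigmoidK numeric(1), link-weight sigmoid steepness and
#'   half-similarity distance (s = 0.005, k = 0.03 on normalised distances).
#' @slot linkThreshold numeric(1), similarity below which links carry negative
#'   weight and are never selected (0.02).
#' @slot stragglerThreshold numeric(1), minimum similarity for attaching an
#'   unchained centroid to a chain (0.02).
#' @slot tMax,tStep numeric(1), SPC temperature grid for centroid trees.
#' @slot distScale numeric(1), multiplier mapping uV waveform distances to the
#'   sigmoid's normalised scale; \code{NA} (default) calibrates it so the
#'   median nearest-neighbour distance between leaf-node mean waveforms of
#'   adjacent trees maps to k.
#' @slot shiftRange integer(1), +/- sample shifts for the translation-invariant
#'   chain-merge distance.
#' @slot maxAntichains numeric(1), per-tree antichain cap for the exact fusion
#'   solver; beyond it the greedy fallback is used.
#' @slot maxExactWork numeric(1), cap on total exact-solver matching work.
#' @exportClass FusionParams
setClass("FusionParams",
  representation(
    centroidsPerBlock = "integer", treesPerIlp = "integer",
    ilpOverlap = "integer", sigmoidS = "numeric", sigmoidK = "numeric",
    linkThreshold = "numeric", stragglerThreshold = "numeric",
    tMax = "numeric", tStep = "numeric", distScale = "numeric",
    shiftRange = "integer", maxAntichains = "numeric", maxExactWork = "numeric"
  ),
  prototype(
    centroidsPerBlock = 1000L, treesPerIlp = 10L, ilpOverlap = 5L,
    sigmoidS = 0.005, sigmoidK = 0.03, linkThreshold = 0.02,
    stragglerThreshold = 0.02, tMax = 0.10, tStep = 0.01,
    distScale = NA_real_, shiftRange = 8L,
    maxAntichains = 4000, maxExactWork = 5e7
  ),
  validity = function(object) {
    msg <- character()
    if (object@ilpOverlap <= 0L || object@ilpOverlap >= object@treesPerIlp)
      msg <- c(msg, "ilpOverlap must be in (0, treesPerIlp)")
    thr <- c(object@linkThreshold, object@stragglerThreshold)
    if (any(thr <= 0) || any(thr >= 1))
      msg <- c(msg, "thresholds must lie in (0, 1)")
    if (object@sigmoidS <= 0 || object@sigmoidK <= 0)
      msg <- c(msg, "sigmoidS and sigmoidK must be positive")
    if (length(msg)) msg else TRUE
  }
)

#' @rdname FusionParams-class
#' @param ... slot values overriding the defaults.
#' @return A \code{FusionParams} object.
#' @export
fusionParams <- function(...) new("FusionParams", ...)

#' Chains of centroids tracking single units (Step-2 output)
#'
#' Disjoint, time-extended sequences of centroid indices, each a putative
#' single unit tracked through waveform drift.
#'
#' @slot chains list of integer vectors of centroid indices, each ordered by
#'   centroid median time.
#' @slot unassigned integer, centroid indices in no chain.
#' @slot nCentroids integer(1), centroids in the fused set.
#' @slot log list of solver/stitching diagnostics.
#' @exportClass ChainSet
setClass("ChainSet",
  representation(
    chains = "list", unassigned = "integer", nCentroids = "integer",
    log = "list"
  ),
  validity = function(object) {
    msg <- character()
    all_c <- unlist(object@chains, use.names = FALSE)
    if (anyDuplicated(all_c)) msg <- c(msg, "chains must be disjoint")
    if (length(intersect(all_c, object@unassigned)))
      msg <- c(msg, "unassigned centroids cannot be chain members")
    if (length(all_c) && max(c(all_c, object@unassigned)) > object@nCentroids)
      msg <- c(msg, "centroid index out of range")
    if (length(msg)) msg else TRUE
  }
)

#' Geometric random-walk amplitude drift model
#'
#' Spike amplitudes follow a bounded geometric random walk: over a lag dt the
#' walk is multiplied by exp(sqrt(beta * dt) * eps) and clipped to
#' [bMin, bMax]; each emitted spike additionally carries independent
#' signal-dependent variability (1 + alpha * eps'). eps, eps' ~ N(0, 1).
#'
#' @slot alpha numeric(1), signal-dependent noise scale (0.1).
#' @slot beta numeric(1), random-walk variance rate, 1/s (1e-6).
#' @slot bMin numeric(1), lower amplitude bound, uV (75).
#' @slot bMaxRange numeric(2), truncation range for the per-electrode bMax
#'   draw, uV (150--400).
#' @slot bMaxExponent numeric(1), exponential-density rate of the bMax draw,
#'   1/uV (0.005).
#' @slot refractory numeric(1), absolute refractory period, s (0.0015).
#' @exportClass AmplitudeDriftModel
setClass("AmplitudeDriftModel",
  representation(
    alpha = "numeric", beta = "numeric", bMin = "numeric",
    bMaxRange = "numeric", bMaxExponent = "numeric", refractory = "numeric"
  ),
  prototype(
    alpha = 0.1, beta = 1e-6, bMin = 75, bMaxRange = c(150, 400),
    bMaxExponent = 0.005, refractory = 0.0015
  ),
  validity = function(object) {
    msg <- character()
    if (object@alpha < 0 || object@beta < 0)
      msg <- c(msg, "alpha and beta must be non-negative")
    if (object@bMin >= object@bMaxRange[1])
      msg <- c(msg, "bMin must be below the bMax range")
    if (length(msg)) msg else TRUE
  }
)

#' @rdname AmplitudeDriftModel-class
#' @param ... slot values overriding the defaults.
#' @return An \code{AmplitudeDriftModel} object.
#' @export
driftModel <- function(...) new("AmplitudeDriftModel", ...)

#' Simulator ground truth
#'
#' Per-unit spike times and emitted amplitudes for a synthetic recording,
#' plus the multi-unit background events and the simulation parameters.
#'
#' @slot units data.frame with one row per unit: \code{id}, \code{tetrode},
#'   \code{cellClass}, \code{rate} (Hz), \code{bMax} (uV), \code{snr}.
#' @slot spikeTimes list of numeric vectors, seconds (1/300000 s precision).
#' @slot amplitudes list of numeric vectors, emitted peak amplitude, uV.
#' @slot background list with \code{times}, \code{amplitudes}, \code{tetrode}.
#' @slot templates list of unit spike templates.
#' @slot params list of simulation settings, including the seed.
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(
    units = "data.frame", spikeTimes = "list", amplitudes = "list",
    background = "list", templates = "list", params = "list"
  ),
  validity = function(object) {
    msg <- character()
    n <- nrow(object@units)
    if (length(object@spikeTimes) != n || length(object@amplitudes) != n)
      msg <- c(msg, "spikeTimes and amplitudes must have one entry per unit")
    if (length(msg)) msg else TRUE
  }
)
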