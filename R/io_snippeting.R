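#' Read and write raw recordings (flat int16 + JSON sidecar)
#'
#' Raw recordings are stored as a flat little-endian int16 binary file,
#' channel-interleaved (all channels of sample 1, then sample 2, ...), next to
#' a JSON sidecar \code{<prefix>.json} holding \code{sample_rate},
#' \code{n_channels}, \code{uv_per_bit}, \code{tetrode_map} and the segment
#' table. \code{readRawRecording} returns a file-backed \code{RawRecording};
#' samples are pulled on demand with \code{readSamples}.
#'
#' @param prefix path prefix; data go to \code{<prefix>.bin}, metadata to
#'   \code{<prefix>.json}.
#' @param rec a \code{RawRecording}.
#' @return \code{readRawRecording}: a \code{RawRecording};
#'   \code{writeRawRecording}: the prefix, invisibly.
#' @export
readRawRecording <- function(prefix) {
  sidecar <- paste0(prefix, ".json")
  bin <- paste0(prefix, ".bin")
  if (!file.exists(sidecar) || !file.exists(bin))
    stop("missing raw recording files: ", prefix, ".{bin,json}")
  meta <- jsonlite::fromJSON(sidecar, simplifyVector = TRUE)
  need <- c("sample_rate", "n_channels", "uv_per_bit", "tetrode_map",
            "segments", "format")
  if (!all(need %in% names(meta)))
    stop("raw recording sidecar is missing fields: ",
         paste(setdiff(need, names(meta)), collapse = ", "))
  if (!identical(meta$format, "fastsort-raw-v1"))
    stop("unsupported raw recording format: ", meta$format)
  n_samples <- file.size(bin) / (2 * meta$n_channels)
  if (n_samples != floor(n_samples))
    stop("binary file size inconsistent with channel count")
  tm <- lapply(meta$tetrode_map, as.integer)
  seg <- matrix(as.numeric(unlist(meta$segments)), ncol = 2, byrow = FALSE,
                dimnames = list(NULL, c("start", "end")))
  if (is.list(meta$segments))
    seg <- cbind(start = as.numeric(meta$segments$start),
                 end = as.numeric(meta$segments$end))
  rawRecording(path = bin, nChannels = as.integer(meta$n_channels),
               nSamples = n_samples, sampleRate = meta$sample_rate,
               uvPerBit = meta$uv_per_bit, tetrodeMap = tm, segments = seg)
}

#' @rdname readRawRecording
#' @export
writeRawRecording <- function(rec, prefix) {
  stopifnot(is(rec, "RawRecording"))
  bin <- paste0(prefix, ".bin")
  if (is.null(rec@path)) {
    con <- file(bin, "wb")
    on.exit(close(con))
    step <- 1e6
    for (s0 in seq(1, ncol(rec@samples), by = step)) {
      s1 <- min(ncol(rec@samples), s0 + step - 1)
      writeBin(as.integer(rec@samples[, s0:s1]), con, size = 2,
               endian = "little")
    }
  } else if (normalizePath(rec@path) != normalizePath(bin, mustWork = FALSE)) {
    file.copy(rec@path, bin, overwrite = TRUE)
  }
  meta <- list(format = "fastsort-raw-v1",
               sample_rate = rec@sampleRate,
               n_channels = rec@nChannels,
               uv_per_bit = rec@uvPerBit,
               tetrode_map = rec@tetrodeMap,
               segments = list(start = rec@segments[, "start"],
                               end = rec@segments[, "end"]))
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' Read a span of samples from a recording
#'
#' @param rec a \code{RawRecording}.
#' @param from,to 1-based inclusive sample range.
#' @param uv if \code{TRUE}, return microvolts instead of ADC counts.
#' @return numeric matrix [channels x (to - from + 1)].
#' @export
readSamples <- function(rec, from = 1, to = rec@nSamples, uv = FALSE) {
  stopifnot(from >= 1, to <= rec@nSamples, to >= from)
  n <- to - from + 1
  if (is.null(rec@path)) {
    x <- rec@samples[, from:to, drop = FALSE]
    storage.mode(x) <- "double"
  } else {
    con <- file(rec@path, "rb")
    on.exit(close(con))
    seek(con, (from - 1) * 2 * rec@nChannels)
    v <- readBin(con, "integer", n = n * rec@nChannels, size = 2,
                 signed = TRUE, endian = "little")
    x <- matrix(as.double(v), nrow = rec@nChannels)
  }
  if (uv) x * rec@uvPerBit else x
}

bandpass_filter <- function(params, sample_rate) {
  signal::ellip(4, params@filterRipple, params@filterAttenuation,
                params@band / (sample_rate / 2), type = "pass")
}

# zero-phase band-pass of a [channels x time] matrix; rows filtered
# independently. Signals shorter than the filter settling length are passed
# through untouched (caller flags them).
filter_matrix <- function(x, filt) {
  min_len <- 6L * (length(filt$b) - 1L) + 2L
  if (ncol(x) < min_len) return(list(x = x, filtered = FALSE))
  for (ch in seq_len(nrow(x)))
    x[ch, ] <- cpp_filtfilt(filt$b, filt$a, x[ch, ])
  list(x = x, filtered = TRUE)
}

#' Band-pass filter and common-median reference a recording
#'
#' Applies the fourth-order elliptic band-pass (default 300--7500 Hz) forward
#' and reverse (zero phase) to every channel, processing each acquisition
#' segment in \code{blockLen}-second blocks padded by \code{pad} seconds on
#' each side (padding is discarded after filtering), then subtracts the
#' per-sample median across channels to cancel common-mode noise.
#'
#' @param rec a \code{RawRecording}.
#' @param params a \code{DetectionParams}.
#' @return numeric matrix [channels x nSamples] in uV. Samples outside any
#'   segment are zero.
#' @export
filterAndReference <- function(rec, params = detectionParams()) {
  out <- matrix(0, rec@nChannels, rec@nSamples)
  walk_blocks(rec, params, function(core_uv, core_range, ...) {
    out[, core_range[1]:core_range[2]] <<- core_uv
    NULL
  })
  out
}

# Iterate over padded filter blocks of a recording. fn receives the filtered,
# referenced core block (uV, channels x core samples), the global core sample
# range, the padded filtered matrix, the global padded range, and the segment
# bounds. Returns fn results invisibly (list), plus a log attribute.
walk_blocks <- function(rec, params, fn) {
  fs <- rec@sampleRate
  filt <- bandpass_filter(params, fs)
  blk <- round(params@blockLen * fs)
  pad <- round(params@pad * fs)
  res <- list()
  log <- list(short_segments = 0L)
  for (s in seq_len(nrow(rec@segments))) {
    seg0 <- rec@segments[s, "start"]
    seg1 <- rec@segments[s, "end"]
    starts <- seq(seg0, seg1, by = blk)
    for (b0 in starts) {
      b1 <- min(b0 + blk - 1, seg1)
      p0 <- max(seg0, b0 - pad)
      p1 <- min(seg1, b1 + pad)
      x <- readSamples(rec, p0, p1, uv = TRUE)
      f <- filter_matrix(x, filt)
      if (!f$filtered) log$short_segments <- log$short_segments + 1L
      x <- f$x
      # noise scale per channel, estimated before referencing: the median of
      # only 4 channels carries a share of every spike and of the noise, so
      # the referenced MAD underestimates the effective noise scale
      mads <- cpp_row_mads(x)
      if (nrow(x) > 1) {
        med <- cpp_col_medians(x)
        x <- sweep(x, 2, med, "-")
      }
      core <- x[, (b0 - p0 + 1):(ncol(x) - (p1 - b1)), drop = FALSE]
      res[[length(res) + 1L]] <-
        fn(core, c(b0, b1), x, c(p0, p1), c(seg0, seg1), mads)
    }
  }
  structure(invisible(res), log = log)
}

#' Detect spikes and extract snippets from a filtered block
#'
#' Threshold-crossing detection on the across-channel absolute maximum of an
#' already filtered, referenced voltage block. After a crossing the event peak
#' is the local maximum of that signal; the detector re-arms once the signal
#' has stayed below \code{returnThreshold} x MAD for \code{returnSamples}
#' consecutive samples. Each event yields a snippet of \code{prePeak} samples,
#' the peak, and \code{postPeak} samples on every channel.
#'
#' @param filtered numeric matrix [channels x time], uV (the tetrode's 4
#'   channels).
#' @param params a \code{DetectionParams}.
#' @param madValue MAD of the filtered signal in uV; estimated from
#'   \code{filtered} when \code{NULL}.
#' @param offset global sample index of the first column minus one (snippet
#'   peak times are reported as \code{offset + local index}).
#' @param keepRange optional global sample range (length 2); events peaking
#'   outside it are dropped (used for block-overlap deduplication).
#' @param tetrode tetrode id stored in the result.
#' @param sampleRate sampling rate, Hz.
#' @return A \code{SnippetSet}. Events whose snippet would cross the block
#'   bounds are discarded and counted in the \code{log} slot.
#' @export
detectSpikes <- function(filtered, params = detectionParams(), madValue = NULL,
                         offset = 0, keepRange = NULL, tetrode = 1L,
                         sampleRate = 30000) {
  stopifnot(is.matrix(filtered))
  if (is.null(madValue))
    madValue <- stats::median(apply(filtered, 1, cpp_mad))
  thr <- if (is.finite(params@thresholdMadMultiple))
    params@thresholdMadMultiple * madValue else params@detectThreshold
  rthr <- params@returnThreshold * madValue
  v <- cpp_absmax_rows(filtered)
  peaks <- cpp_detect_peaks(v, thr, rthr, params@returnSamples)
  pre <- params@prePeak
  post <- params@postPeak
  n_edge <- 0L
  keep <- logical(length(peaks))
  for (i in seq_along(peaks)) {
    p <- peaks[i]
    gp <- offset + p
    if (!is.null(keepRange) && (gp < keepRange[1] || gp > keepRange[2])) next
    if (p - pre < 1 || p + post > ncol(filtered)) {
      n_edge <- n_edge + 1L
      next
    }
    keep[i] <- TRUE
  }
  peaks <- peaks[keep]
  sps <- pre + post + 1L
  wf <- if (length(peaks))
    cpp_gather_snippets(filtered, peaks, pre, post)
  else matrix(0, 0, nrow(filtered) * sps)
  new("SnippetSet", peakTimes = offset + as.numeric(peaks), waveforms = wf,
      tetrode = as.integer(tetrode), nChannels = nrow(filtered),
      samplesPerSpike = pre + post + 1L, sampleRate = sampleRate,
      params = params, segments = cbind(start = 1, end = ncol(filtered)),
      log = list(edge_discarded = n_edge, mad = madValue))
}

#' Detect and snippet a whole recording
#'
#' Runs the full spike-identification front end: blockwise zero-phase
#' band-pass filtering, common-median referencing, per-block MAD estimation,
#' and threshold-crossing snippet extraction independently for each tetrode.
#'
#' @param rec a \code{RawRecording}.
#' @param params a \code{DetectionParams}.
#' @param tetrodes tetrode ids to process (default: all).
#' @return A named list of \code{SnippetSet}, one per tetrode.
#' @export
snippetRecording <- function(rec, params = detectionParams(),
                             tetrodes = names(rec@tetrodeMap)) {
  acc <- lapply(tetrodes, function(t) list(times = list(), wf = list(),
                                           edge = 0L, mads = numeric()))
  names(acc) <- tetrodes
  pre <- params@prePeak
  post <- params@postPeak
  walk_blocks(rec, params, function(core, core_range, padded, pad_range, seg,
                                    mads) {
    for (t in tetrodes) {
      chans <- rec@tetrodeMap[[t]]
      x <- padded[chans, , drop = FALSE]
      madv <- stats::median(mads[chans])
      # snippets must not cross the segment bounds
      lim <- c(max(pad_range[1], seg[1] + pre), min(pad_range[2], seg[2] - post))
      ss <- detectSpikes(x, params, madValue = madv,
                         offset = pad_range[1] - 1,
                         keepRange = c(max(core_range[1], lim[1]),
                                       min(core_range[2], lim[2])),
                         tetrode = match(t, tetrodes),
                         sampleRate = rec@sampleRate)
      if (nSpikes(ss)) {
        acc[[t]]$times[[length(acc[[t]]$times) + 1L]] <<- ss@peakTimes
        acc[[t]]$wf[[length(acc[[t]]$wf) + 1L]] <<- ss@waveforms
      }
      acc[[t]]$edge <<- acc[[t]]$edge + ss@log$edge_discarded
      acc[[t]]$mads <<- c(acc[[t]]$mads, madv)
    }
    NULL
  })
  out <- list()
  for (t in tetrodes) {
    a <- acc[[t]]
    acc[[t]] <- list()  # drop the accumulator's reference to the blocks
    times <- unlist(a$times, use.names = FALSE)
    # fill a preallocated matrix block by block, releasing blocks as we go,
    # to avoid rbind's transient second copy on large recordings
    n_all <- if (length(a$wf)) sum(vapply(a$wf, nrow, 0L)) else 0L
    wf <- matrix(0, n_all,
                 if (length(a$wf)) ncol(a$wf[[1]]) else 4 * (pre + post + 1L))
    at <- 1L
    for (b in seq_along(a$wf)) {
      nb <- nrow(a$wf[[b]])
      if (nb) wf[at:(at + nb - 1L), ] <- a$wf[[b]]
      at <- at + nb
      a$wf[b] <- list(NULL)
    }
    if (is.null(times)) times <- numeric()
    out[[t]] <- new("SnippetSet", peakTimes = times, waveforms = wf,
        tetrode = match(t, tetrodes), nChannels = length(rec@tetrodeMap[[t]]),
        samplesPerSpike = pre + post + 1L, sampleRate = rec@sampleRate,
        params = params, segments = rec@segments,
        log = list(edge_discarded = a$edge, mad = stats::median(a$mads)))
  }
  out[tetrodes]
}

#' Extract the local field potential stream
#'
#' Decimates the raw recording 100-fold (e.g. 30 kHz to 300 Hz) by two
#' applications of a fourth-order 5-fold decimating Chebyshev filter followed
#' by one fourth-order 4-fold decimating Chebyshev filter.
#'
#' @param rec a \code{RawRecording} whose sample rate is divisible by 100.
#' @return numeric matrix [channels x floor(nSamples / 100)] in uV at
#'   \code{sampleRate / 100} Hz.
#' @export
extractLfp <- function(rec) {
  if (rec@sampleRate %% 100 != 0)
    stop("sample rate must be divisible by 100")
  x <- readSamples(rec, uv = TRUE)
  n_out <- floor(ncol(x) / 100)
  out <- matrix(0, nrow(x), n_out)
  for (ch in seq_len(nrow(x))) {
    y <- signal::decimate(x[ch, ], 5, n = 4, ftype = "iir")
    y <- signal::decimate(y, 5, n = 4, ftype = "iir")
    y <- signal::decimate(y, 4, n = 4, ftype = "iir")
    out[ch, ] <- y[seq_len(n_out)]
  }
  out
}

#' Snippet, centroid and chain stores
#'
#' Versioned on-disk containers for the pipeline's intermediate results.
#' Round-trips are bit-exact; reading a file with a different format tag or a
#' missing field raises an explicit format error.
#'
#' @param x a \code{SnippetSet}, \code{CentroidSet} or \code{ChainSet}.
#' @param path file path.
#' @return The reader returns the stored object; writers return \code{path}
#'   invisibly.
#' @export
writeSnippetStore <- function(x, path) write_store(x, path, "SnippetSet")

#' @rdname writeSnippetStore
#' @export
readSnippetStore <- function(path) read_store(path, "SnippetSet")

#' @rdname writeSnippetStore
#' @export
writeCentroidStore <- function(x, path) write_store(x, path, "CentroidSet")

#' @rdname writeSnippetStore
#' @export
readCentroidStore <- function(path) read_store(path, "CentroidSet")

#' @rdname writeSnippetStore
#' @export
writeChainStore <- function(x, path) write_store(x, path, "ChainSet")

#' @rdname writeSnippetStore
#' @export
readChainStore <- function(path) read_store(path, "ChainSet")

store_tag <- function(class) paste0("fastsort-", tolower(class), "-v1")

write_store <- function(x, path, class) {
  stopifnot(is(x, class))
  saveRDS(list(format = store_tag(class), object = x), path)
  invisible(path)
}

read_store <- function(path, class) {
  obj <- readRDS(path)
  if (!is.list(obj) || !identical(obj$format, store_tag(class)))
    stop("not a fastsort ", class, " store: ", path)
  if (!is(obj$object, class)) stop("corrupt ", class, " store: ", path)
  validObject(obj$object)
  obj$object
}
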