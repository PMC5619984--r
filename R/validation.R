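#' Match a sorted spike train against ground truth
#'
#' Greedy nearest-neighbour one-to-one matching: candidate (truth, sorted)
#' pairs within \code{tolerance} are taken in order of increasing time
#' difference, each spike matched at most once. The error rate is
#' (false positives + false negatives) / (ground-truth spikes), so it can
#' exceed 1.
#'
#' @param sortedTimes,truthTimes sorted numeric spike times, s.
#' @param tolerance matching tolerance, s (default 1 ms).
#' @return list with \code{tp}, \code{fp}, \code{fn}, \code{errorRate} and
#'   the matched index pairs. With empty truth the error rate is \code{NA}.
#' @export
matchSpikeTrains <- function(sortedTimes, truthTimes, tolerance = 1e-3) {
  if (is.unsorted(sortedTimes) || is.unsorted(truthTimes))
    stop("spike trains must be sorted")
  nt <- length(truthTimes)
  ns <- length(sortedTimes)
  if (!nt)
    return(list(tp = 0L, fp = ns, fn = 0L, errorRate = NA_real_,
                pairs = cbind(truth = integer(), sorted = integer())))
  ti <- integer()
  si <- integer()
  dt <- numeric()
  if (ns) {
    lo <- findInterval(truthTimes - tolerance, sortedTimes) + 1L
    hi <- findInterval(truthTimes + tolerance, sortedTimes)
    for (i in seq_len(nt)) {
      if (lo[i] > hi[i]) next
      js <- lo[i]:hi[i]
      ti <- c(ti, rep.int(i, length(js)))
      si <- c(si, js)
      dt <- c(dt, abs(sortedTimes[js] - truthTimes[i]))
    }
  }
  used_t <- logical(nt)
  used_s <- logical(ns)
  pairs <- list()
  for (r in order(dt, ti, si)) {
    if (used_t[ti[r]] || used_s[si[r]]) next
    used_t[ti[r]] <- TRUE
    used_s[si[r]] <- TRUE
    pairs[[length(pairs) + 1L]] <- c(ti[r], si[r])
  }
  tp <- length(pairs)
  fp <- ns - tp
  fn <- nt - tp
  pm <- if (tp) do.call(rbind, pairs) else cbind(integer(), integer())
  colnames(pm) <- c("truth", "sorted")
  list(tp = tp, fp = fp, fn = fn, errorRate = (fp + fn) / nt, pairs = pm)
}

#' Ground-truth spike times from an intracellular trace
#'
#' High-pass filters the intracellular voltage (third-order Butterworth,
#' zero phase) and detects peaks exceeding \code{sdThreshold} standard
#' deviations of the baseline noise (estimated robustly as 1.4826 x MAD).
#'
#' @param trace numeric intracellular voltage vector.
#' @param sampleRate Hz.
#' @param highpass cut-off frequency, Hz.
#' @param sdThreshold detection threshold in baseline SDs.
#' @return numeric vector of spike times, s.
#' @export
intracellularSpikeTimes <- function(trace, sampleRate, highpass = 250,
                                    sdThreshold = 4) {
  filt <- signal::butter(3, highpass / (sampleRate / 2), type = "high")
  x <- signal::filtfilt(filt, trace)
  sigma <- stats::mad(x)
  if (sigma == 0) return(numeric())
  peaks <- cpp_detect_peaks(x, sdThreshold * sigma, sigma, 8L)
  as.numeric(peaks) / sampleRate
}

# top-nPc principal-component projections per channel
channel_pca_features <- function(wf, nChannels, nPc = 3) {
  sps <- ncol(wf) / nChannels
  out <- matrix(0, nrow(wf), nChannels * nPc)
  for (ch in seq_len(nChannels)) {
    x <- wf[, ((ch - 1) * sps + 1):(ch * sps), drop = FALSE]
    mu <- colMeans(x)
    xc <- sweep(x, 2, mu)
    v <- eigen(crossprod(xc) / max(nrow(x) - 1, 1), symmetric = TRUE)$vectors
    out[, ((ch - 1) * nPc + 1):(ch * nPc)] <- xc %*% v[, seq_len(nPc)]
  }
  out
}

#' Best ellipsoidal error rate (BEER)
#'
#' Optimality baseline for stationary clustering: for each unit, a support
#' vector machine with a quadratic (polynomial degree-2) boundary is trained
#' on spike features (top 3 principal-component projections per channel, 12
#' features per tetrode snippet) to separate the unit's spikes from all other
#' detected spikes, on a training subset; classification cost ratios are swept
#' over two orders of magnitude to trace a ROC curve, and the BEER is the
#' minimum of (false positives + false negatives) / (unit spikes) on the test
#' subset.
#'
#' @param snippets waveform matrix [spikes x features] or a \code{SnippetSet}.
#' @param labels integer unit labels per snippet (0 = unmatched/background).
#' @param seed integer seed for the train/test split.
#' @param nCosts cost ratios (log-spaced over \code{costRange}).
#' @param costRange relative false-positive/false-negative cost range.
#' @param maxPerSet cap on training and test subset sizes.
#' @param minSpikes units with fewer spikes are skipped with a warning.
#' @param nChannels channels per snippet.
#' @param features optional precomputed feature matrix (rows = spikes);
#'   bypasses the per-channel PCA and \code{snippets} may then be NULL.
#' @return data.frame with one row per evaluated unit: \code{unit},
#'   \code{beer}, \code{nTruthTest}, \code{bestCost}.
#' @export
beerErrorRate <- function(snippets, labels, seed = NULL, nCosts = 10,
                          costRange = c(0.1, 10), maxPerSet = 1e5,
                          minSpikes = 100, nChannels = 4, features = NULL) {
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  feats <- if (!is.null(features)) as.matrix(features) else {
    wf <- if (is(snippets, "SnippetSet")) waveforms(snippets) else
      as.matrix(snippets)
    channel_pca_features(wf, nChannels)
  }
  stopifnot(nrow(feats) == length(labels))
  n <- nrow(feats)
  idx <- sample.int(n)
  half <- n %/% 2
  train <- idx[seq_len(min(half, maxPerSet))]
  test <- idx[(half + 1):min(n, half + maxPerSet)]
  costs <- exp(seq(log(costRange[1]), log(costRange[2]), length.out = nCosts))
  units <- sort(setdiff(unique(labels), 0))
  rows <- list()
  for (u in units) {
    if (sum(labels == u) < minSpikes) {
      warning("unit ", u, " has fewer than ", minSpikes, " spikes; skipped")
      next
    }
    ytr <- factor(labels[train] == u, levels = c(FALSE, TRUE))
    yte <- labels[test] == u
    n_truth <- sum(yte)
    if (n_truth == 0 || all(ytr == "TRUE") || !any(ytr == "TRUE")) next
    best <- Inf
    best_cost <- NA_real_
    for (cw in costs) {
      fit <- e1071::svm(feats[train, , drop = FALSE], ytr,
                        kernel = "polynomial", degree = 2, coef0 = 1,
                        class.weights = c("FALSE" = 1, "TRUE" = cw))
      pred <- stats::predict(fit, feats[test, , drop = FALSE]) == "TRUE"
      err <- (sum(pred & !yte) + sum(!pred & yte)) / n_truth
      if (err < best) {
        best <- err
        best_cost <- cw
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(unit = u, beer = best,
                                            nTruthTest = n_truth,
                                            bestCost = best_cost)
  }
  if (length(rows)) do.call(rbind, rows)
  else data.frame(unit = integer(), beer = numeric(), nTruthTest = integer(),
                  bestCost = numeric())
}
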