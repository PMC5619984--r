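#' Log-binned inter-spike-interval histogram
#'
#' 50 log-spaced bins spanning ISIs from 1 ms to 1000 s, normalised to sum 1
#' (all-zero when the train has no in-range ISIs).
#'
#' @param times sorted spike times, s.
#' @param nBins number of bins.
#' @param range ISI range, s.
#' @return numeric vector of bin probabilities.
#' @export
isiHistogram <- function(times, nBins = 50, range = c(0.001, 1000)) {
  breaks <- exp(seq(log(range[1]), log(range[2]), length.out = nBins + 1))
  isi <- diff(sort(times))
  isi <- isi[isi >= range[1] & isi <= range[2]]
  h <- as.numeric(table(cut(isi, breaks, include.lowest = TRUE)))
  if (sum(h) > 0) h / sum(h) else h
}

#' Firing-rate similarity
#'
#' 1 - 2 |FRi - FRj| / (FRi + FRj): 1 for identical rates, -1 when exactly one
#' rate is 0 (maximum dissimilarity). Undefined (NA) when both rates are 0.
#'
#' @param fri,frj non-negative firing rates, Hz.
#' @return similarity in [-1, 1], or NA.
#' @export
frSimilarity <- function(fri, frj) {
  stopifnot(all(fri >= 0), all(frj >= 0))
  out <- 1 - 2 * abs(fri - frj) / (fri + frj)
  out[fri + frj == 0] <- NA_real_
  out
}

#' ISI-distribution similarity between two trains
#'
#' Pearson correlation between the normalised log-binned ISI histograms of
#' two spike trains; NA when either train has fewer than \code{minIsi} ISIs.
#'
#' @param a,b spike-time vectors, s.
#' @param minIsi minimum ISIs per histogram.
#' @param ... passed to \code{\link{isiHistogram}}.
#' @return Pearson r in [-1, 1], or NA.
#' @export
isiSimilarity <- function(a, b, minIsi = 100, ...) {
  if (length(a) - 1 < minIsi || length(b) - 1 < minIsi) return(NA_real_)
  suppressWarnings(stats::cor(isiHistogram(a, ...), isiHistogram(b, ...)))
}

#' Similarity records across days
#'
#' Builds the table of similarity values used for stability analysis:
#' within-unit comparisons across day lags, and across-unit comparisons
#' within the same day restricted to units of the same putative type.
#'
#' @param dayData per-unit list; each element a named list (names = day
#'   numbers) of spike-time vectors (\code{metric = "isi"}) or firing rates
#'   (\code{metric = "rate"}).
#' @param types optional character vector of per-unit putative types.
#' @param metric \code{"isi"} or \code{"rate"}.
#' @param ... passed to \code{\link{isiSimilarity}}.
#' @return data.frame with \code{scope} (within/across), \code{unitA},
#'   \code{unitB}, \code{dayA}, \code{dayB}, \code{lag}, \code{value}.
#' @export
similarityRecords <- function(dayData, types = NULL,
                              metric = c("isi", "rate"), ...) {
  metric <- match.arg(metric)
  fun <- switch(metric,
    isi = function(a, b) isiSimilarity(a, b, ...),
    rate = function(a, b) frSimilarity(a, b))
  rows <- list()
  nu <- length(dayData)
  for (u in seq_len(nu)) {
    days <- as.numeric(names(dayData[[u]]))
    if (length(days) > 1)
      for (i in seq_len(length(days) - 1)) for (j in (i + 1):length(days))
        rows[[length(rows) + 1L]] <- data.frame(
          scope = "within", unitA = u, unitB = u,
          dayA = days[i], dayB = days[j], lag = days[j] - days[i],
          value = fun(dayData[[u]][[i]], dayData[[u]][[j]]))
  }
  if (nu > 1)
    for (a in seq_len(nu - 1)) for (b in (a + 1):nu) {
      if (!is.null(types) && types[a] != types[b]) next
      shared <- intersect(names(dayData[[a]]), names(dayData[[b]]))
      for (d in shared)
        rows[[length(rows) + 1L]] <- data.frame(
          scope = "across", unitA = a, unitB = b,
          dayA = as.numeric(d), dayB = as.numeric(d), lag = 0,
          value = fun(dayData[[a]][[d]], dayData[[b]][[d]]))
    }
  if (length(rows)) do.call(rbind, rows)
  else data.frame(scope = character(), unitA = integer(), unitB = integer(),
                  dayA = numeric(), dayB = numeric(), lag = numeric(),
                  value = numeric())
}

#' Cluster-quality metrics per hour block
#'
#' Computes, for every unit and consecutive one-hour block, the isolation
#' distance and L-ratio in the standard 16-dimensional feature space (per
#' channel: waveform peak, energy, and projections on the first two principal
#' components of all spikes in the block) plus the fraction of inter-spike
#' intervals violating a 2 ms refractory period.
#'
#' Isolation distance is the squared Mahalanobis distance (with respect to
#' the unit's feature covariance) of the n-th closest non-member spike, n the
#' unit size; it is undefined when non-members are fewer than members.
#' L-ratio is sum over non-members of 1 - pchisq(D2, df) divided by the unit
#' size. Singular covariances are ridge-regularised.
#'
#' @param times spike times of all tetrode events, s.
#' @param labels unit label per event (0 = unassigned noise).
#' @param wf waveform matrix [events x (channels * samples)], uV.
#' @param nChannels channels per event.
#' @param blockSec quality block length, s.
#' @param refractory ISI violation threshold, s.
#' @param ridge covariance regularisation factor.
#' @return data.frame: \code{unit}, \code{block}, \code{n},
#'   \code{isolationDistance}, \code{lRatio}, \code{isiViolation}.
#' @export
clusterQuality <- function(times, labels, wf, nChannels = 4,
                           blockSec = 3600, refractory = 0.002,
                           ridge = 1e-8) {
  stopifnot(length(times) == length(labels), nrow(wf) == length(times))
  sps <- ncol(wf) / nChannels
  blocks <- floor(times / blockSec)
  rows <- list()
  for (bl in sort(unique(blocks))) {
    sel <- which(blocks == bl)
    feats <- quality_features(wf[sel, , drop = FALSE], nChannels, sps)
    df <- ncol(feats)
    labs <- labels[sel]
    for (u in sort(setdiff(unique(labs), 0))) {
      mem <- which(labs == u)
      oth <- which(labs != u)
      n_u <- length(mem)
      iso <- NA_real_
      lr <- NA_real_
      if (n_u > df && length(oth)) {
        mu <- colMeans(feats[mem, , drop = FALSE])
        cv <- stats::cov(feats[mem, , drop = FALSE])
        cv <- cv + diag(ridge * mean(diag(cv)) + 1e-12, df)
        d2 <- try(stats::mahalanobis(feats[oth, , drop = FALSE], mu, cv),
                  silent = TRUE)
        if (!inherits(d2, "try-error")) {
          lr <- sum(1 - stats::pchisq(d2, df)) / n_u
          if (length(oth) >= n_u) iso <- sort(d2)[n_u]
        }
      }
      ut <- sort(times[sel][mem])
      isi <- diff(ut)
      viol <- if (length(isi)) mean(isi < refractory) else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        unit = u, block = bl, n = n_u, isolationDistance = iso,
        lRatio = lr, isiViolation = viol)
    }
  }
  if (length(rows)) do.call(rbind, rows)
  else data.frame(unit = integer(), block = integer(), n = integer(),
                  isolationDistance = numeric(), lRatio = numeric(),
                  isiViolation = numeric())
}

quality_features <- function(wf, nChannels, sps) {
  out <- matrix(0, nrow(wf), nChannels * 4)
  for (ch in seq_len(nChannels)) {
    x <- wf[, ((ch - 1) * sps + 1):(ch * sps), drop = FALSE]
    peak <- apply(abs(x), 1, max)
    energy <- sqrt(rowSums(x^2))
    mu <- colMeans(x)
    xc <- sweep(x, 2, mu)
    v <- eigen(crossprod(xc) / max(nrow(x) - 1, 1), symmetric = TRUE)$vectors
    pc <- xc %*% v[, 1:2, drop = FALSE]
    out[, (ch - 1) * 4 + 1:4] <- cbind(peak, energy, pc)
  }
  out
}

#' Signal-to-noise ratio of a unit
#'
#' Average spike amplitude divided by a consistent estimator of the baseline
#' standard deviation (the MAD of the filtered recording times 1.4826),
#' reported as the maximum across the channels.
#'
#' @param meanWaveform the unit's mean waveform: numeric vector (channels
#'   concatenated) or [channels x samples] matrix, uV.
#' @param trace optional filtered recording [channels x time] from which the
#'   per-channel MAD is estimated.
#' @param madUv per-channel (or scalar) MAD in uV, used when \code{trace} is
#'   not given.
#' @param nChannels channels (for vector input).
#' @return SNR (unitless).
#' @export
snrEstimate <- function(meanWaveform, trace = NULL, madUv = NULL,
                        nChannels = 4) {
  m <- if (is.matrix(meanWaveform)) meanWaveform
    else matrix(meanWaveform, nChannels, length(meanWaveform) / nChannels,
                byrow = TRUE)
  if (!is.null(trace)) {
    madUv <- apply(trace, 1, function(r) stats::mad(r, constant = 1))
  }
  if (is.null(madUv)) stop("either trace or madUv is required")
  if (any(madUv <= 0)) stop("trace MAD must be positive")
  amp <- apply(abs(m), 1, max)
  max(amp / (madUv * 1.4826))
}

#' Cross-correlogram with jitter-null significance
#'
#' Counts spike-time lags of train b relative to train a in 1 ms bins over a
#' +/- \code{windowMs} window, smoothed with a 3 ms boxcar. For same-tetrode
#' pairs the zero-lag bin (structurally empty, one event per ms per tetrode)
#' is replaced by the mean of its neighbours before smoothing. Significance:
#' the correlation is significant when two consecutive bins exceed the mean
#' of a shuffled correlogram (each spike of b jittered by +/-
#' \code{jitterMs}) by three standard deviations of the shuffled correlogram's
#' bins; it is only evaluable when the trains together have at least
#' \code{minSpikes} spikes. The normalised amplitude is the correlogram
#' extremum (mean of 3 bins around the peak or trough) divided by the average
#' shuffled bin height, so values > 1 indicate positive and < 1 negative
#' correlation; the lag is the extremum's bin.
#'
#' @param a,b sorted spike-time vectors, s.
#' @param sameTetrode apply the zero-lag fix.
#' @param binMs,windowMs,smoothMs,jitterMs correlogram geometry, ms.
#' @param minSpikes combined spike count below which significance is NA.
#' @param nShuffles jitter realisations for the null.
#' @param seed integer seed for the jitter.
#' @return list: \code{lags} (s), \code{counts}, \code{smoothed},
#'   \code{shuffled}, \code{amplitude}, \code{lag} (s), \code{significant},
#'   \code{evaluable}.
#' @export
crossCorrelogram <- function(a, b, sameTetrode = FALSE, binMs = 1,
                             windowMs = 100, smoothMs = 3, jitterMs = 400,
                             minSpikes = 5000, nShuffles = 1, seed = NULL) {
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  binw <- binMs / 1000
  half <- round(windowMs / binMs)
  raw <- cpp_lag_counts(sort(a), sort(b), binw, half)
  z <- half + 1L
  if (sameTetrode) raw[z] <- (raw[z - 1] + raw[z + 1]) / 2
  smooth <- boxcar(raw, round(smoothMs / binMs))
  shuf <- matrix(0, nShuffles, length(raw))
  for (s in seq_len(nShuffles)) {
    bj <- sort(b + stats::runif(length(b), -jitterMs / 1000, jitterMs / 1000))
    sc <- cpp_lag_counts(sort(a), bj, binw, half)
    shuf[s, ] <- boxcar(sc, round(smoothMs / binMs))
  }
  shuf_mean <- mean(shuf)
  shuf_sd <- stats::sd(as.numeric(shuf))
  evaluable <- (length(a) + length(b)) >= minSpikes
  above <- smooth > shuf_mean + 3 * shuf_sd
  significant <- if (evaluable) any(above[-1] & above[-length(above)])
    else NA
  dev <- smooth - shuf_mean
  ext <- which.max(abs(dev))
  around <- max(1, ext - 1):min(length(smooth), ext + 1)
  amplitude <- if (shuf_mean > 0) mean(smooth[around]) / shuf_mean
    else NA_real_
  lags <- (seq_along(raw) - z) * binw
  list(lags = lags, counts = raw, smoothed = smooth,
       shuffled = colMeans(shuf), amplitude = amplitude, lag = lags[ext],
       significant = significant, evaluable = evaluable)
}

boxcar <- function(x, w) {
  if (w <= 1) return(x)
  y <- stats::filter(x, rep(1 / w, w), sides = 2)
  y <- as.numeric(y)
  y[is.na(y)] <- x[is.na(y)]
  y
}

#' Classify units into putative cell types
#'
#' K-means (k = 2) on each unit's peak-normalised mean waveform concatenated
#' with its log-transformed firing rate. The cluster with the higher mean
#' firing rate (narrow, fast-spiking units) is labelled
#' \code{"fast_spiking"}; the other \code{"regular"}. Initial centers are the
#' means of the lower and upper halves of the units ordered by log rate, so
#' the labelling is deterministic and invariant to unit order.
#'
#' @param meanWaveforms matrix [units x features], uV.
#' @param rates per-unit mean firing rates, Hz.
#' @return character vector of labels.
#' @export
classifyCellTypes <- function(meanWaveforms, rates) {
  stopifnot(nrow(meanWaveforms) == length(rates), length(rates) >= 2)
  wfn <- meanWaveforms / apply(abs(meanWaveforms), 1, max)
  lr <- log(pmax(rates, 1e-3))
  feats <- cbind(wfn, lr)
  ord <- order(lr)
  lohalf <- ord[seq_len(floor(length(ord) / 2))]
  hihalf <- setdiff(ord, lohalf)
  centers <- rbind(colMeans(feats[lohalf, , drop = FALSE]),
                   colMeans(feats[hihalf, , drop = FALSE]))
  if (all(centers[1, ] == centers[2, ])) {
    out <- character(length(rates))
    out[lohalf] <- "regular"
    out[hihalf] <- "fast_spiking"
    return(out)
  }
  km <- stats::kmeans(feats, centers = centers)
  fs <- which.max(tapply(rates, km$cluster, mean))
  ifelse(km$cluster == fs, "fast_spiking", "regular")
}

#' Per-unit stability index
#'
#' Ordinary least-squares slope of a similarity metric against day lag. A
#' unit is stable when the slope is at least \code{slopeThreshold} (-0.025
#' per day) and its p-value is at least \code{pThreshold} (0.05), i.e. there
#' is no substantial, statistically significant negative trend.
#'
#' @param lags day lags (at least 3 distinct values).
#' @param values similarity values at those lags.
#' @param slopeThreshold,pThreshold stability criteria.
#' @return list: \code{slope} (per day), \code{p}, \code{stable}. All NA when
#'   fewer than 3 distinct lags carry data.
#' @export
stabilityIndex <- function(lags, values, slopeThreshold = -0.025,
                           pThreshold = 0.05) {
  ok <- is.finite(lags) & is.finite(values)
  if (length(unique(lags[ok])) < 3)
    return(list(slope = NA_real_, p = NA_real_, stable = NA))
  fit <- stats::lm(values[ok] ~ lags[ok])
  co <- suppressWarnings(summary(fit))$coefficients  # zero-variance fits
  slope <- co[2, 1]
  p <- co[2, 4]
  if (!is.finite(p)) p <- 1  # zero-variance fit: no evidence of a trend
  list(slope = slope, p = p,
       stable = slope >= slopeThreshold && p >= pThreshold)
}
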