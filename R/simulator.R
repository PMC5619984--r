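#' Parametric spike-template library
#'
#' Builds unit spike templates as biphasic/triphasic difference-of-Gaussian
#' shapes sampled at 10x the acquisition rate (300 kHz for 30 kHz recordings),
#' so spikes can be rendered at sub-sample phases (emulating alignment jitter
#' from acquisition). Each template has a dominant channel with unit peak
#' amplitude and attenuated copies on the other channels; the 30 kHz phase-0
#' view has absolute peak 1 at sample 32 (31 samples precede the peak).
#' Narrow-spike templates are tagged interneurons and carry higher firing
#' rates; firing rates are drawn log-uniformly (principal cells over
#' \code{rateRange}, interneurons over the upper part of it), spanning the
#' roughly three orders of magnitude seen in cortical and striatal units.
#'
#' @param n number of templates.
#' @param fracInterneuron fraction of narrow, fast-spiking templates.
#' @param rateRange firing-rate range, Hz.
#' @param nChannels channels per tetrode.
#' @param samplesPerSpike snippet length at the acquisition rate.
#' @param seed integer seed.
#' @return list of templates: \code{shape} (high-resolution waveform, peak at
#'   index \code{peakIndex}), \code{channelWeights}, \code{rate},
#'   \code{cellClass}, \code{waveform} (phase-0 [channels x samples] view).
#' @export
makeTemplateLibrary <- function(n, fracInterneuron = 0.2,
                                rateRange = c(0.03, 40), nChannels = 4L,
                                samplesPerSpike = 64L, seed = NULL) {
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  up <- 10L
  width <- samplesPerSpike + 16L  # extra tail samples on each side
  half <- width %/% 2L
  n_in <- round(fracInterneuron * n)
  classes <- rep(c("interneuron", "principal"), c(n_in, n - n_in))
  lapply(seq_len(n), function(i) {
    narrow <- classes[i] == "interneuron"
    # broad parameter ranges: real spike libraries span narrow symmetric
    # biphasic to wide asymmetric triphasic shapes, and two units rarely
    # share a waveform
    s1 <- if (narrow) stats::runif(1, 0.05, 0.13) else stats::runif(1, 0.12, 0.45)
    s2 <- s1 * stats::runif(1, 1.2, 3.2)
    delta <- s1 * stats::runif(1, 1.2, 3.5)
    r2 <- stats::runif(1, 0.15, 0.8)
    r0 <- stats::runif(1, 0, 0.45)  # pre-bump, either polarity
    r0 <- r0 * sample(c(-1, 1), 1)
    ahp <- stats::runif(1, 0, 0.25)  # slow after-wave
    tt <- (seq_len(width * up) - half * up) / (30 * up)  # ms relative to peak
    shape <- -exp(-tt^2 / (2 * s1^2)) +
      r2 * exp(-(tt - delta)^2 / (2 * s2^2)) +
      r0 * exp(-(tt + delta)^2 / (2 * (1.5 * s1)^2)) -
      ahp * exp(-(tt - 2.5 * delta)^2 / (2 * (3 * s2)^2))
    pk <- which.max(abs(shape))
    # re-centre the peak onto the phase grid and normalise to unit peak
    target <- half * up + 1L
    shape <- shift_pad(shape, target - pk)
    shape <- shape / max(abs(shape))
    w <- c(1, stats::runif(nChannels - 1, 0.15, 0.6))
    w <- w[sample.int(nChannels)]
    rate <- if (narrow)
      exp(stats::runif(1, log(max(2, rateRange[1])), log(rateRange[2])))
    else exp(stats::runif(1, log(rateRange[1]), log(rateRange[2])))
    j <- (-(samplesPerSpike %/% 2 - 1L)):(samplesPerSpike %/% 2)
    phase0 <- shape[target + up * j]
    list(shape = shape, peakIndex = target, up = up, width = width,
         channelWeights = w, dominant = which.max(w), rate = rate,
         cellClass = classes[i],
         waveform = outer(w, phase0))
  })
}

shift_pad <- function(x, by) {
  n <- length(x)
  out <- numeric(n)
  src <- seq_len(n) - by
  ok <- src >= 1 & src <= n
  out[ok] <- x[src[ok]]
  out
}

# [channels x width] template rendered at sub-sample phase p (0..up-1),
# sampled at the acquisition rate; column j corresponds to relative sample
# j - pre - 1 from the event's base sample.
template_phase <- function(tmpl, p) {
  sps <- tmpl$width - 16L
  j <- (-(sps %/% 2 + 7L)):(sps %/% 2 + 8L)  # full padded support
  idx <- tmpl$peakIndex + tmpl$up * j - p
  idx[idx < 1 | idx > length(tmpl$shape)] <- NA
  v <- tmpl$shape[idx]
  v[is.na(v)] <- 0
  outer(tmpl$channelWeights, v)
}

#' Simulate a refractory Poisson spike train
#'
#' Homogeneous Poisson process with an absolute refractory period (dead-time
#' model: each inter-spike interval is the refractory period plus an
#' exponential with the nominal rate), so the realised rate is
#' rate / (1 + rate * refractory). Times are quantised to 1/300000 s.
#'
#' @param rate nominal rate, Hz.
#' @param duration train duration, s.
#' @param refractory absolute refractory period, s.
#' @param seed integer seed.
#' @return sorted numeric vector of spike times in (0, duration].
#' @export
simulateSpikeTrain <- function(rate, duration, refractory = 0.0015,
                               seed = NULL) {
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  if (rate <= 0 || duration <= 0) return(numeric())
  times <- numeric()
  t_last <- 0
  repeat {
    n_draw <- max(100L, ceiling((duration - t_last) * rate * 1.2))
    isi <- refractory + stats::rexp(n_draw, rate)
    tt <- t_last + cumsum(isi)
    times <- c(times, tt[tt <= duration])
    t_last <- tt[length(tt)]
    if (t_last > duration) break
  }
  round(times * 3e5) / 3e5
}

#' Simulate a bounded geometric random-walk amplitude trajectory
#'
#' Evaluates the drift model at the given spike times: between consecutive
#' spikes separated by dt the walk is multiplied by exp(sqrt(beta * dt) * eps)
#' and clipped to [bMin, bMax]; each emitted amplitude is the walk value times
#' (1 + alpha * eps') with an independent standard-normal eps' per spike.
#'
#' @param model an \code{\linkS4class{AmplitudeDriftModel}}.
#' @param A0 initial amplitude at time 0, uV (within the walk bounds).
#' @param spikeTimes sorted spike times, s.
#' @param bMax upper walk bound for this electrode, uV.
#' @param seed integer seed.
#' @return list with \code{walk} and \code{amplitude} (uV, one per spike).
#' @export
simulateAmplitudeTrajectory <- function(model, A0, spikeTimes,
                                        bMax = model@bMaxRange[2],
                                        seed = NULL) {
  if (is.unsorted(spikeTimes)) stop("spikeTimes must be sorted")
  stopifnot(A0 >= model@bMin, A0 <= bMax)
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  n <- length(spikeTimes)
  if (!n) return(list(walk = numeric(), amplitude = numeric()))
  dt <- diff(c(0, spikeTimes))
  eps <- stats::rnorm(n)
  walk <- numeric(n)
  a <- A0
  for (i in seq_len(n)) {
    a <- a * exp(sqrt(model@beta * dt[i]) * eps[i])
    a <- min(max(a, model@bMin), bMax)
    walk[i] <- a
  }
  list(walk = walk, amplitude = walk * (1 + model@alpha * stats::rnorm(n)))
}

draw_bmax <- function(n, model) {
  lam <- model@bMaxExponent
  lo <- model@bMaxRange[1]
  hi <- model@bMaxRange[2]
  u <- stats::runif(n)
  lo - log(1 - u * (1 - exp(-lam * (hi - lo)))) / lam
}

#' Render a synthetic drifting tetrode recording with ground truth
#'
#' Simulates long-term extracellular data: per tetrode, \code{unitsPerTetrode}
#' foreground units (a fixed fraction of them interneurons) drawn from a
#' parametric template library fire as refractory Poisson processes with
#' spike times at 1/300000 s precision; each spike is rendered at its
#' sub-sample phase from the 10x-upsampled template, scaled by the unit's
#' bounded geometric random-walk amplitude (independent signal-dependent
#' variability per spike), and summed linearly into band-limited Gaussian
#' baseline noise. Low-amplitude multi-unit background activity
#' (\code{backgroundUnits} units at \code{backgroundRate} Hz each, amplitudes
#' Gaussian around the detection threshold, truncated at 0) is added the same
#' way. Identical configuration and seed reproduce the recording bit for bit.
#'
#' @param duration recording duration, s.
#' @param nTetrodes tetrodes (4 channels each).
#' @param unitsPerTetrode foreground units per tetrode.
#' @param model an \code{AmplitudeDriftModel}.
#' @param fracInterneuron fraction of interneuron templates per tetrode.
#' @param rateRange foreground firing-rate range, Hz.
#' @param backgroundUnits,backgroundRate multi-unit background population.
#' @param backgroundAmpMean,backgroundAmpSd background amplitude (uV),
#'   Gaussian truncated at 0.
#' @param noiseMad baseline noise MAD, uV.
#' @param sampleRate acquisition rate, Hz.
#' @param uvPerBit ADC scale.
#' @param seed integer seed.
#' @param rates optional explicit per-unit firing rates (Hz), recycled across
#'   tetrodes; by default rates are drawn with the templates (log-uniform
#'   over \code{rateRange}).
#' @param dir directory for the flat binary file; recordings larger than
#'   ~40 M samples are always file-backed (default \code{tempdir()}).
#' @param chunkSec rendering chunk, s.
#' @return list with \code{recording} (a \code{RawRecording}) and
#'   \code{truth} (a \code{\linkS4class{GroundTruth}}).
#' @export
renderSyntheticRecording <- function(duration, nTetrodes = 1L,
                                     unitsPerTetrode = 8L,
                                     model = driftModel(),
                                     fracInterneuron = 0.2,
                                     rateRange = c(0.03, 40),
                                     backgroundUnits = 40L,
                                     backgroundRate = 0.5,
                                     backgroundAmpMean = 50,
                                     backgroundAmpSd = 25,
                                     noiseMad = 7.6,
                                     sampleRate = 30000, uvPerBit = 0.195,
                                     seed = NULL, rates = NULL, dir = NULL,
                                     chunkSec = 30) {
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  n_ch <- 4L * nTetrodes
  n_samp <- floor(duration * sampleRate)
  n_units <- nTetrodes * unitsPerTetrode
  templates <- makeTemplateLibrary(n_units, fracInterneuron = fracInterneuron,
                                   rateRange = rateRange)
  templates <- templates[sample.int(n_units)]  # spread classes over tetrodes
  unit_rates <- if (is.null(rates)) vapply(templates, `[[`, 0, "rate") else
    rep_len(rates, n_units)
  units <- data.frame(id = seq_len(n_units),
                      tetrode = rep(seq_len(nTetrodes), each = unitsPerTetrode),
                      templateId = seq_len(n_units),
                      cellClass = vapply(templates, `[[`, "", "cellClass"),
                      rate = unit_rates)
  bmax_ch <- draw_bmax(n_ch, model)
  units$bMax <- vapply(seq_len(n_units), function(u) {
    ch0 <- (units$tetrode[u] - 1L) * 4L
    bmax_ch[ch0 + templates[[u]]$dominant]
  }, 0)
  units$A0 <- stats::runif(n_units, model@bMin, units$bMax)
  spike_times <- vector("list", n_units)
  amps <- vector("list", n_units)
  walks <- vector("list", n_units)
  for (u in seq_len(n_units)) {
    spike_times[[u]] <- simulateSpikeTrain(units$rate[u], duration,
                                           model@refractory)
    tr <- simulateAmplitudeTrajectory(model, units$A0[u], spike_times[[u]],
                                      bMax = units$bMax[u])
    amps[[u]] <- tr$amplitude
    walks[[u]] <- tr$walk
  }
  units$snr <- vapply(seq_len(n_units), function(u)
    if (length(amps[[u]])) mean(abs(amps[[u]])) / (noiseMad * 1.4826) else 0, 0)
  # multi-unit background: per tetrode, backgroundUnits distinct templates
  bg_templates <- makeTemplateLibrary(backgroundUnits * nTetrodes,
                                      fracInterneuron = fracInterneuron,
                                      rateRange = rateRange)
  bg <- list(times = numeric(), amplitudes = numeric(), unit = integer(),
             tetrode = integer())
  for (b in seq_len(backgroundUnits * nTetrodes)) {
    tt <- simulateSpikeTrain(backgroundRate, duration, model@refractory)
    aa <- stats::rnorm(length(tt), backgroundAmpMean, backgroundAmpSd)
    aa <- pmax(aa, 0)
    bg$times <- c(bg$times, tt)
    bg$amplitudes <- c(bg$amplitudes, aa)
    bg$unit <- c(bg$unit, rep(b, length(tt)))
    bg$tetrode <- c(bg$tetrode, rep((b - 1L) %/% backgroundUnits + 1L,
                                    length(tt)))
  }
  ord <- order(bg$times)
  bg <- lapply(bg, `[`, ord)

  # noise shaping filter and its empirical MAD calibration; the noise stream
  # itself uses a fast generator seeded from R's RNG, so everything remains
  # reproducible through the seed
  nyq <- sampleRate / 2
  nf <- signal::butter(4, pmin(c(300, 7500), nyq * 0.98) / nyq, type = "pass")
  noise_seed <- floor(stats::runif(1) * 2^31)
  calib <- cpp_noise_chunk(noise_seed, 100000, nf$b, nf$a, numeric(), 1)$y
  noise_scale <- noiseMad / cpp_mad(calib[-(1:5000)])

  in_memory <- n_samp * n_ch <= 4e7
  con <- NULL
  if (!in_memory) {
    if (is.null(dir)) dir <- tempdir()
    bin_path <- file.path(dir, sprintf("synthetic-%d.bin",
                                       as.integer(stats::runif(1, 1, 1e9))))
    con <- file(bin_path, "wb")
    on.exit(if (!is.null(con)) close(con), add = TRUE)
  } else {
    mem <- matrix(0L, n_ch, n_samp)
  }
  chunk <- round(chunkSec * sampleRate)
  zstate <- vector("list", n_ch)
  # warm the filters up so the first chunk is already stationary noise
  for (ch in seq_len(n_ch))
    zstate[[ch]] <- cpp_noise_chunk(noise_seed + ch, 5000, nf$b, nf$a,
                                    numeric(), 1)$z
  chunk_id <- 0L
  # per-unit event geometry: base sample (1-based) and sub-sample phase
  ev <- lapply(seq_len(n_units), function(u) {
    k <- round(spike_times[[u]] * sampleRate * 10)
    list(base = as.integer(k %/% 10 + 1L), phase = as.integer(k %% 10))
  })
  bg_k <- round(bg$times * sampleRate * 10)
  bg_base <- as.integer(bg_k %/% 10 + 1L)
  bg_phase <- as.integer(bg_k %% 10)
  half_w <- 40L
  for (c0 in seq(1L, n_samp, by = chunk)) {
    c1 <- min(c0 + chunk - 1L, n_samp)
    len <- c1 - c0 + 1L
    chunk_id <- chunk_id + 1L
    sig <- matrix(0, n_ch, len)
    for (ch in seq_len(n_ch)) {
      f <- cpp_noise_chunk(noise_seed + 1000 * chunk_id + ch, len, nf$b, nf$a,
                           zstate[[ch]], noise_scale)
      zstate[[ch]] <- f$z
      sig[ch, ] <- f$y
    }
    for (u in seq_len(n_units)) {
      sel <- which(ev[[u]]$base >= c0 - half_w & ev[[u]]$base <= c1 + half_w)
      if (!length(sel)) next
      ch0 <- (units$tetrode[u] - 1L) * 4L
      for (p in unique(ev[[u]]$phase[sel])) {
        s <- sel[ev[[u]]$phase[sel] == p]
        tm <- template_phase(templates[[u]], p)
        at <- ev[[u]]$base[s] - (ncol(tm) %/% 2L - 1L) - (c0 - 1L)
        cpp_add_events(sig, tm, at, amps[[u]][s], ch0)
      }
    }
    sel <- which(bg_base >= c0 - half_w & bg_base <= c1 + half_w)
    if (length(sel)) {
      for (b in unique(bg$unit[sel])) {
        sb <- sel[bg$unit[sel] == b]
        ch0 <- (bg$tetrode[sb[1]] - 1L) * 4L
        for (p in unique(bg_phase[sb])) {
          s <- sb[bg_phase[sb] == p]
          tm <- template_phase(bg_templates[[b]], p)
          at <- bg_base[s] - (ncol(tm) %/% 2L - 1L) - (c0 - 1L)
          cpp_add_events(sig, tm, at, bg$amplitudes[s], ch0)
        }
      }
    }
    counts <- cpp_to_counts(sig, uvPerBit)
    if (in_memory) {
      mem[, c0:c1] <- counts
    } else {
      writeBin(counts, con, size = 2, endian = "little")
    }
  }
  tmap <- lapply(seq_len(nTetrodes), function(i) ((i - 1L) * 4L) + 1:4)
  names(tmap) <- as.character(seq_len(nTetrodes))
  rec <- if (in_memory) {
    rawRecording(samples = mem, sampleRate = sampleRate, uvPerBit = uvPerBit,
                 tetrodeMap = tmap)
  } else {
    close(con)
    con <- NULL
    rawRecording(path = bin_path, nChannels = n_ch, nSamples = n_samp,
                 sampleRate = sampleRate, uvPerBit = uvPerBit,
                 tetrodeMap = tmap)
  }
  truth <- new("GroundTruth", units = units, spikeTimes = spike_times,
               amplitudes = amps,
               background = list(times = bg$times,
                                 amplitudes = bg$amplitudes,
                                 tetrode = bg$tetrode),
               templates = templates,
               params = list(seed = seed, duration = duration, model = model,
                             noiseMad = noiseMad, walks = walks,
                             backgroundRate = backgroundRate,
                             backgroundUnits = backgroundUnits))
  list(recording = rec, truth = truth)
}
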