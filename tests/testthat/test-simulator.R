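test_that("degenerate drift model emits constant amplitudes", {
  m <- driftModel(alpha = 0, beta = 0)
  tr <- simulateAmplitudeTrajectory(m, 123, 1:100, seed = 1)
  expect_true(all(tr$walk == 123))
  expect_true(all(tr$amplitude == 123))
})

test_that("walk log-increments have SD sqrt(beta * dt) before clipping", {
  m <- driftModel(alpha = 0, beta = 1e-6, bMin = 1e-3)
  tr <- simulateAmplitudeTrajectory(m, 200, seq_len(20000), bMax = 1e9,
                                    seed = 2)
  # wide bounds: no clipping, increments are exactly sqrt(beta)*eps at dt=1
  inc <- diff(log(tr$walk))
  expect_equal(sd(inc), 1e-3, tolerance = 0.03)
  expect_equal(mean(inc), 0, tolerance = 3e-5)
})

test_that("walk values respect the amplitude bounds", {
  m <- driftModel(alpha = 0.1, beta = 1e-4)
  tr <- simulateAmplitudeTrajectory(m, 100, seq_len(5000), bMax = 300,
                                    seed = 3)
  expect_gte(min(tr$walk), 75)
  expect_lte(max(tr$walk), 300)
  expect_error(simulateAmplitudeTrajectory(m, 100, c(3, 1, 2)), "sorted")
})

test_that("refractory Poisson trains have the dead-time rate and no short ISIs", {
  expect_equal(simulateSpikeTrain(0, 100), numeric())
  st <- simulateSpikeTrain(100, 500, refractory = 0.0015, seed = 4)
  expect_gte(min(diff(st)), 0.0015 - 1e-9)  # quantisation-safe
  want <- 100 / (1 + 100 * 0.0015)
  expect_equal(length(st) / 500, want, tolerance = 0.03)
})

test_that("40 background units at 0.5 Hz pool to about 20 Hz", {
  set.seed(5)
  n <- sum(vapply(1:40, function(i)
    length(simulateSpikeTrain(0.5, 1e4)), 0))
  rate <- n / 1e4
  se <- sqrt(n) / 1e4
  expect_lt(abs(rate - 20), 3 * se + 0.02)
})

test_that("six 8-unit tetrodes yield 48 ground-truth units", {
  sim <- renderSyntheticRecording(5, nTetrodes = 6, seed = 6)
  expect_equal(nrow(sim$truth@units), 48L)
  expect_equal(sim$recording@nChannels, 24L)
  expect_equal(length(sim$recording@tetrodeMap), 6L)
  expect_equal(sort(unique(sim$truth@units$tetrode)), 1:6)
  # about 20% interneurons per draw
  expect_equal(sum(sim$truth@units$cellClass == "interneuron"),
               round(48 * 0.2))
})

test_that("seeded renders are bit-identical", {
  a <- renderSyntheticRecording(3, seed = 7)
  b <- renderSyntheticRecording(3, seed = 7)
  expect_identical(readSamples(a$recording), readSamples(b$recording))
  expect_identical(a$truth@spikeTimes, b$truth@spikeTimes)
  expect_identical(a$truth@amplitudes, b$truth@amplitudes)
})

test_that("noise-only recordings produce few threshold crossings", {
  sim <- renderSyntheticRecording(30, unitsPerTetrode = 0L,
                                  backgroundUnits = 0L, seed = 8)
  sn <- snippetRecording(sim$recording,
                         detectionParams(thresholdMadMultiple = 7))[[1]]
  # false events are rare: the threshold sits at ~4.7 sigma of the
  # across-channel maximum of referenced noise
  expect_lt(nSpikes(sn) / 30, 2)
})

test_that("ground-truth spikes of a strong unit are recovered by detection", {
  # a ~200 uV unit in 7.6 uV-MAD noise; signal-dependent variability kept so
  # amplitudes vary spike to spike
  sim <- renderSyntheticRecording(30, unitsPerTetrode = 1L,
                                  backgroundUnits = 0L, seed = 9,
                                  model = driftModel(beta = 0, bMin = 350,
                                                     bMaxRange = c(390, 400)))
  u <- 1
  truth <- sim$truth@spikeTimes[[u]]
  sn <- snippetRecording(sim$recording,
                         detectionParams(thresholdMadMultiple = 7))[[1]]
  mt <- matchSpikeTrains(peakTimes(sn) / 30000, truth, tolerance = 1e-3)
  # every isolated spike is detected (rare refractory-scale collisions merge)
  expect_lte(mt$fn, ceiling(0.05 * length(truth)))
  # alignment is consistent: detected peaks sit at a fixed small offset from
  # the ground-truth peak tick (zero-phase filtering reshapes the extremum)
  off <- round(peakTimes(sn)[mt$pairs[, "sorted"]] -
                 truth[mt$pairs[, "truth"]] * 30000)
  expect_lte(abs(median(off)), 3)
  expect_gte(mean(abs(off - median(off)) <= 3), 0.9)
  # rendered peak amplitude tracks the trajectory amplitude
  got <- vapply(truth, function(t) {
    s <- round(t * 30000) + 1
    max(abs(readSamples(sim$recording, s - 3, s + 6, uv = TRUE)))
  }, 0)
  expect_gte(cor(got, sim$truth@amplitudes[[u]]), 0.95)
})

test_that("disabling drift makes first/last mean waveforms agree", {
  sim <- renderSyntheticRecording(40, unitsPerTetrode = 2L,
                                  backgroundUnits = 0L, seed = 10,
                                  model = driftModel(beta = 0))
  sn <- snippetRecording(sim$recording,
                         detectionParams(thresholdMadMultiple = 7))[[1]]
  tt <- peakTimes(sn) / 30000
  first <- colMeans(waveforms(sn)[tt < 20, , drop = FALSE])
  last <- colMeans(waveforms(sn)[tt >= 20, , drop = FALSE])
  # difference well under the per-sample noise floor (MAD ~ 5 uV)
  expect_lt(sqrt(mean((first - last)^2)), 5)
})

test_that("templates are peak-normalised at the alignment sample", {
  tl <- makeTemplateLibrary(10, seed = 11)
  for (tm in tl) {
    w <- tm$waveform
    dom <- tm$dominant
    expect_equal(max(abs(w)), 1)
    expect_equal(abs(w[dom, 32]), 1)
  }
  classes <- vapply(tl, `[[`, "", "cellClass")
  expect_equal(sum(classes == "interneuron"), 2L)
})
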