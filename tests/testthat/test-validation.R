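test_that("spike-train matching reproduces constructed error rates", {
  truth <- sort(runif(100, 0, 100))
  # identical trains: zero error
  m0 <- matchSpikeTrains(truth, truth)
  expect_equal(m0$errorRate, 0)
  # drop 10, add 5 spurious: error (10 + 5) / 100
  set.seed(51)
  sorted <- sort(c(truth[-(1:10)], runif(5, 200, 300)))
  m1 <- matchSpikeTrains(sorted, truth)
  expect_equal(m1$errorRate, 0.15)
  expect_equal(m1$fn, 10L)
  expect_equal(m1$fp, 5L)
  # all spikes shifted by 2x tolerance: nothing matches, error = 2
  m2 <- matchSpikeTrains(truth + 0.002, truth, tolerance = 1e-3)
  expect_equal(m2$errorRate, 2)
  # empty truth: undefined
  expect_true(is.na(matchSpikeTrains(sorted, numeric())$errorRate))
})

test_that("matching is one-to-one and invariant to global time shifts", {
  set.seed(52)
  truth <- sort(runif(200, 0, 50))
  sorted <- sort(truth + rnorm(200, sd = 2e-4))
  m <- matchSpikeTrains(sorted, truth)
  expect_equal(nrow(m$pairs), m$tp)
  expect_false(anyDuplicated(m$pairs[, "truth"]) > 0)
  expect_false(anyDuplicated(m$pairs[, "sorted"]) > 0)
  m_shift <- matchSpikeTrains(sorted + 1000, truth + 1000)
  expect_equal(m_shift$errorRate, m$errorRate)
})

test_that("intracellular ground truth finds inserted suprathreshold spikes", {
  fs <- 20000
  set.seed(53)
  n <- fs * 10
  trace <- rnorm(n)
  at <- sort(sample(seq(fs, n - fs, by = 401), 50))
  spike_sd <- sd(fastsort:::cpp_filtfilt(
    signal::butter(3, 250 / (fs / 2), type = "high")$b,
    signal::butter(3, 250 / (fs / 2), type = "high")$a, trace))
  shape <- 10 * exp(-((-20:20) / 4)^2)
  for (a in at) trace[a + (-20:20)] <- trace[a + (-20:20)] + shape
  got <- intracellularSpikeTimes(trace, fs)
  # every inserted spike is found (plus a handful of 4-sigma noise events)
  m <- matchSpikeTrains(got, (at + 1) / fs, tolerance = 3 / fs)
  expect_equal(m$fn, 0L)
  expect_lte(m$fp, 15L)
  # flat trace: none
  expect_equal(length(intracellularSpikeTimes(rep(0, 1000), fs)), 0L)
  # 3-SD spikes stay below the 4-SD threshold
  weak <- rnorm(n)
  for (a in at) weak[a] <- weak[a] + 3
  mw <- matchSpikeTrains(intracellularSpikeTimes(weak, fs), (at + 1) / fs,
                         tolerance = 3 / fs)
  expect_lte(mw$tp, 10L)
})

test_that("BEER is near 0 for separable clouds and near 1 at chance", {
  set.seed(54)
  n <- 1200
  wf_a <- matrix(rnorm(n / 2 * 256), n / 2, 256) + 30
  wf_b <- matrix(rnorm(n / 2 * 256), n / 2, 256) - 30
  labels <- rep(c(1L, 0L), each = n / 2)
  res <- beerErrorRate(rbind(wf_a, wf_b), labels, seed = 1, nCosts = 5)
  expect_equal(res$beer, 0, tolerance = 0.02)
  # fully overlapping balanced clouds: (FP + FN) / truth ~ 1 at best
  wf_c <- matrix(rnorm(n * 256), n, 256)
  labels_c <- rep(c(1L, 0L), each = n / 2)
  res_c <- beerErrorRate(wf_c, labels_c, seed = 2, nCosts = 5)
  expect_gte(res_c$beer, 0.7)
  # feature space is 12-dimensional for tetrode snippets
  f <- fastsort:::channel_pca_features(wf_c, 4)
  expect_equal(ncol(f), 12L)
})

test_that("BEER decreases with cluster separation and skips tiny units", {
  set.seed(55)
  n <- 800
  make <- function(sep) {
    wf <- rbind(matrix(rnorm(n / 2 * 64), n / 2, 64) + sep,
                matrix(rnorm(n / 2 * 64), n / 2, 64))
    beerErrorRate(wf, rep(c(1L, 0L), each = n / 2), seed = 3, nCosts = 5,
                  nChannels = 4)$beer
  }
  errs <- vapply(c(0.2, 1, 4), make, 0)
  expect_true(all(diff(errs) <= 0.05))  # non-increasing up to MC noise
  expect_warning(
    beerErrorRate(matrix(rnorm(300 * 64), 300, 64),
                  c(rep(1L, 50), rep(0L, 250)), seed = 4, minSpikes = 100),
    "skipped")
})
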