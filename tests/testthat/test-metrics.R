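test_that("firing-rate similarity hits its boundary values", {
  expect_equal(frSimilarity(5, 5), 1)
  expect_equal(frSimilarity(5, 0), -1)
  expect_equal(frSimilarity(3, 1), 0)
  expect_equal(frSimilarity(1, 3), frSimilarity(3, 1))  # symmetric
  expect_true(is.na(frSimilarity(0, 0)))
  r <- frSimilarity(runif(100, 0, 50), runif(100, 0, 50))
  expect_true(all(r >= -1 & r <= 1))
})

test_that("ISI histograms are normalised and similarity behaves", {
  set.seed(61)
  train <- cumsum(rexp(5000, 5))
  h <- isiHistogram(train)
  expect_equal(length(h), 50L)
  expect_equal(sum(h), 1)
  expect_equal(isiSimilarity(train, train), 1)
  # exponential vs bursting trains are less similar than within-kind
  t_pois <- cumsum(rexp(3000, 5))
  burst <- as.vector(outer(seq(0, 0.004, by = 0.002),
                           cumsum(rexp(1000, 1)), "+"))
  burst <- sort(burst)
  within <- isiSimilarity(t_pois, cumsum(rexp(3000, 5)))
  across <- isiSimilarity(t_pois, burst)
  expect_gt(within, across)
  expect_true(is.na(isiSimilarity(train[1:50], train)))  # too few ISIs
})

test_that("Poisson ISI violations match the exponential closed form", {
  set.seed(62)
  train <- cumsum(rexp(3e5, 5))
  wf <- matrix(rnorm(length(train) * 8), length(train), 8)
  q <- clusterQuality(train, rep(1L, length(train)), wf, nChannels = 2,
                      blockSec = max(train) + 1)
  want <- 1 - exp(-5 * 0.002)  # 0.00995
  expect_equal(q$isiViolation, want, tolerance = 0.05)
})

test_that("isolation distance and L-ratio match direct Mahalanobis arithmetic", {
  set.seed(63)
  n_u <- 60
  n_o <- 180
  sps <- 8
  wf <- rbind(matrix(rnorm(n_u * sps, sd = 2), n_u, sps) + 40,
              matrix(rnorm(n_o * sps, sd = 6), n_o, sps))
  labs <- rep(c(1L, 0L), c(n_u, n_o))
  times <- sort(runif(n_u + n_o, 0, 100))
  q <- clusterQuality(times, labs, wf, nChannels = 1, blockSec = 1000)
  # independent oracle: build the 4 features (peak, energy, PC1, PC2) by hand
  peak <- apply(abs(wf), 1, max)
  energy <- sqrt(rowSums(wf^2))
  xc <- sweep(wf, 2, colMeans(wf))
  pcs <- xc %*% eigen(crossprod(xc) / (nrow(wf) - 1))$vectors[, 1:2]
  feats <- cbind(peak, energy, pcs)
  mem <- which(labs == 1L)
  mu <- colMeans(feats[mem, ])
  cv <- cov(feats[mem, ])
  cv <- cv + diag(1e-8 * mean(diag(cv)) + 1e-12, 4)
  d2 <- mahalanobis(feats[-mem, ], mu, cv)
  expect_equal(q$isolationDistance, sort(d2)[n_u], tolerance = 1e-6)
  expect_equal(q$lRatio, sum(1 - pchisq(d2, 4)) / n_u, tolerance = 1e-6)
})

test_that("well-separated units pass the quality thresholds, overlapping fail", {
  set.seed(64)
  n <- 400
  sps <- 16
  base <- 120 * exp(-((1:sps - 8) / 2)^2)
  wf_u <- do.call(rbind, replicate(n, as.vector(outer(c(1, .5, .3, .2), base)),
                                   simplify = FALSE)) +
    matrix(rnorm(n * 4 * sps, sd = 5), n)
  wf_noise <- matrix(rnorm(n * 4 * sps, sd = 15), n)
  times <- sort(runif(2 * n, 0, 1800))
  q <- clusterQuality(times, rep(c(1L, 0L), each = n),
                      rbind(wf_u, wf_noise), nChannels = 4)
  expect_gte(q$isolationDistance[1], 25)
  expect_lte(q$lRatio[1], 0.3)
  # unit identical to the noise cloud: poor isolation
  set.seed(640)
  n2 <- 100
  cloud <- matrix(rnorm(5 * n2 * 4 * sps, sd = 15), 5 * n2)
  times2 <- sort(runif(6 * n2, 0, 1800))
  q2 <- clusterQuality(times2, rep(c(1L, 0L), c(n2, 5 * n2)),
                       rbind(cloud[1:n2, ], cloud), nChannels = 4)
  expect_lt(q2$isolationDistance[1], 25)
  expect_gt(q2$lRatio[1], 0.3)
})

test_that("SNR estimator recovers the true amplitude-to-noise ratio", {
  set.seed(65)
  m <- matrix(0, 4, 16)
  m[2, 8] <- 150
  trace <- matrix(rnorm(4 * 2e5, sd = 10), 4, 2e5)
  got <- snrEstimate(m, trace = trace)
  expect_equal(got, 15, tolerance = 0.02)
  expect_equal(snrEstimate(m * 0, madUv = rep(5, 4)), 0)
  expect_equal(snrEstimate(m * 2, madUv = rep(5, 4)),
               2 * snrEstimate(m, madUv = rep(5, 4)))
})

test_that("cross-correlograms detect lagged coupling and stay flat for
           independent trains", {
  set.seed(66)
  a <- cumsum(rexp(6000, 5))
  b <- sort(a + 0.005 + rnorm(length(a), sd = 5e-4))
  cc <- crossCorrelogram(a, b, seed = 1)
  expect_true(cc$evaluable)
  expect_true(cc$significant)
  expect_gt(cc$amplitude, 1.5)
  expect_equal(cc$lag, 0.005, tolerance = 2e-3)
  ind <- crossCorrelogram(a, cumsum(rexp(6000, 5)), seed = 2)
  expect_false(ind$significant)
  expect_equal(ind$amplitude, 1, tolerance = 0.25)
  # too few spikes: significance not evaluable
  small <- crossCorrelogram(a[1:100], b[1:100], seed = 3)
  expect_false(small$evaluable)
  expect_true(is.na(small$significant))
})

test_that("same-tetrode zero-lag fix replaces the structural dip", {
  set.seed(67)
  a <- cumsum(rexp(4000, 3))
  b <- cumsum(rexp(4000, 3))
  # delete coincident spikes as a tetrode detector would
  b <- b[vapply(b, function(t) min(abs(t - a)) > 0.001, TRUE)]
  cc <- crossCorrelogram(a, b, sameTetrode = TRUE, smoothMs = 1, seed = 4)
  z <- which(cc$lags == 0)
  expect_equal(cc$counts[z], mean(cc$counts[c(z - 1, z + 1)]))
})

test_that("autocorrelogram of a train matches a brute-force oracle", {
  set.seed(68)
  a <- cumsum(rexp(800, 10))
  cc <- crossCorrelogram(a, a, sameTetrode = TRUE, smoothMs = 1,
                         windowMs = 20, seed = 5)
  # brute force: all pairwise lags
  lags <- as.vector(outer(a, a, "-"))
  lags <- lags[lags != 0 & abs(lags) <= 0.0205]
  oracle <- vapply(cc$lags, function(l)
    sum(lags >= l - 5e-4 & lags < l + 5e-4), 0)
  z <- which(cc$lags == 0)
  oracle[z] <- mean(oracle[c(z - 1, z + 1)])
  expect_equal(cc$counts[-z], oracle[-z], tolerance = 1e-9)
})

test_that("cell-type classification separates narrow-fast from broad-slow", {
  set.seed(69)
  sps <- 32
  t <- 1:sps
  narrow <- -exp(-((t - 12) / 1.2)^2) + 0.4 * exp(-((t - 16) / 2)^2)
  broad <- -exp(-((t - 12) / 3.5)^2) + 0.4 * exp(-((t - 22) / 6)^2)
  n <- 30
  wf <- rbind(
    do.call(rbind, replicate(n, 80 * narrow + rnorm(sps, sd = 2),
                             simplify = FALSE)),
    do.call(rbind, replicate(n, 150 * broad + rnorm(sps, sd = 2),
                             simplify = FALSE)))
  rates <- c(exp(rnorm(n, log(15), 0.3)), exp(rnorm(n, log(1.5), 0.3)))
  got <- classifyCellTypes(wf, rates)
  truth <- rep(c("fast_spiking", "regular"), each = n)
  expect_gte(mean(got == truth), 0.95)
  # order invariance
  perm <- sample(2 * n)
  got2 <- classifyCellTypes(wf[perm, ], rates[perm])
  expect_identical(got2, got[perm])
  # identical units split deterministically
  same <- classifyCellTypes(wf[rep(1, 6), ], rep(5, 6))
  expect_equal(length(unique(same)), 2L)
})

test_that("stability index flags decaying similarity and spares stable units", {
  const <- stabilityIndex(1:10, rep(0.9, 10))
  expect_equal(const$slope, 0)
  expect_true(const$stable)
  set.seed(70)
  dec <- stabilityIndex(1:10, 1 - 0.05 * (1:10) + rnorm(10, sd = 0.005))
  expect_equal(dec$slope, -0.05, tolerance = 0.02)
  expect_false(dec$stable)
  expect_true(is.na(stabilityIndex(c(1, 2), c(1, 1))$slope))
  # unbiased slope recovery over replicates
  slopes <- vapply(1:300, function(i) {
    y <- 1 - 0.02 * (1:12) + rnorm(12, sd = 0.02)
    stabilityIndex(1:12, y)$slope
  }, 0)
  expect_equal(mean(slopes), -0.02, tolerance = 0.002)
})

test_that("similarity records cover within-unit lags and across-unit days", {
  set.seed(71)
  mk <- function() {
    out <- lapply(1:3, function(d) cumsum(rexp(500, 5)))
    names(out) <- 1:3
    out
  }
  rec <- similarityRecords(list(mk(), mk()), types = c("a", "a"),
                           metric = "isi", minIsi = 50)
  expect_true(all(rec$value[is.finite(rec$value)] <= 1))
  expect_true(any(rec$scope == "within" & rec$lag == 2))
  expect_true(any(rec$scope == "across" & rec$lag == 0))
  rr <- similarityRecords(list(`1` = list(`1` = 5, `2` = 5),
                               `2` = list(`1` = 3)), metric = "rate")
  expect_equal(rr$value[rr$scope == "within"], 1)
})
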