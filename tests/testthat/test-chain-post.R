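# build a ChainSet + CentroidSet + SnippetSet triple from per-chain spike
# times and per-chain template waveforms
make_chain_world <- function(chain_times, templates, fs = 30000, seed = 41) {
  set.seed(seed)
  all_times <- sort(unlist(chain_times))
  n <- length(all_times)
  d <- length(templates[[1]])
  wf <- matrix(0, n, d)
  idx_of <- match(unlist(chain_times), all_times)
  lab <- integer(n)
  k <- 0
  for (ci in seq_along(chain_times)) {
    ix <- idx_of[k + seq_along(chain_times[[ci]])]
    wf[ix, ] <- matrix(templates[[ci]], length(ix), d, byrow = TRUE) +
      rnorm(length(ix) * d, sd = 2)
    lab[ix] <- ci
    k <- k + length(chain_times[[ci]])
  }
  sn <- new("SnippetSet", peakTimes = all_times * fs, waveforms = wf,
            tetrode = 1L, nChannels = 4L, samplesPerSpike = as.integer(d / 4),
            sampleRate = fs, params = detectionParams(),
            segments = cbind(start = 1, end = max(all_times) * fs + 100),
            log = list())
  # one centroid per chain per 10-minute stretch
  cents <- list()
  for (ci in seq_along(chain_times)) {
    tt <- chain_times[[ci]]
    grp <- floor(tt / 600)
    for (g in unique(grp)) {
      mem <- which(lab == ci & floor(all_times / 600) == g)
      cents[[length(cents) + 1L]] <- list(
        wf = colMeans(wf[mem, , drop = FALSE]),
        t = median(all_times[mem]) * fs, mem = mem, chain = ci)
    }
  }
  ord <- order(vapply(cents, `[[`, 0, "t"))
  cents <- cents[ord]
  cent_chain <- vapply(cents, `[[`, 0L, "chain")
  centroids <- new("CentroidSet",
                   waveforms = do.call(rbind, lapply(cents, `[[`, "wf")),
                   medianTimes = vapply(cents, `[[`, 0, "t"),
                   counts = as.integer(lengths(lapply(cents, `[[`, "mem"))),
                   scale = rep(1L, length(cents)),
                   members = lapply(cents, `[[`, "mem"),
                   unassigned = integer(), nChannels = 4L,
                   samplesPerSpike = as.integer(d / 4))
  chains <- lapply(seq_along(chain_times), function(ci)
    which(cent_chain == ci))
  cs <- new("ChainSet", chains = chains, unassigned = integer(),
            nCentroids = length(cents), log = list(distScale = 0.01))
  list(chains = cs, centroids = centroids, snippets = sn)
}

dense_train <- function(from, to, rate = 1) {
  sort(runif(round((to - from) * rate), from, to))
}

test_that("a unit split by a recording gap is reconnected by one proposal", {
  set.seed(42)
  tmpl <- rnorm(64) * 80
  w <- make_chain_world(
    list(dense_train(0, 3600 * 2), dense_train(3600 * 4, 3600 * 6)),
    list(tmpl, tmpl))
  gaps <- cbind(start = 3600 * 2 + 60, end = 3600 * 4 - 60)
  pr <- proposeChainMerges(w$chains, w$centroids, w$snippets,
                           recordingGaps = gaps)
  acc <- pr[pr$decision == "accept", ]
  expect_equal(nrow(acc), 1L)
  expect_equal(c(acc$chainA, acc$chainB), c(1L, 2L))
  expect_gte(acc$waveformCorr, 0.9)
  merged <- applyChainMerges(w$chains, pr)
  expect_equal(length(merged@chains), 1L)
  # merging never duplicates snippets
  expect_false(anyDuplicated(unlist(merged@chains)) > 0)
})

test_that("dissimilar chains one hour apart are rejected", {
  set.seed(43)
  t1 <- rnorm(64) * 80
  t2 <- rnorm(64) * 80  # independent random waveform: low correlation
  # different firing statistics too, so the ISI criterion cannot rescue it
  bursty <- sort(as.vector(outer(seq(0, 0.02, by = 0.004),
                                 sort(runif(1500, 3600 * 3, 3600 * 5)), "+")))
  w <- make_chain_world(
    list(dense_train(0, 3600 * 2), bursty),
    list(t1, t2))
  pr <- proposeChainMerges(w$chains, w$centroids, w$snippets)
  expect_true(all(pr$decision == "reject"))
})

test_that("a chain matching two successors is flagged, not merged", {
  set.seed(44)
  tmpl <- rnorm(64) * 80
  w <- make_chain_world(
    list(dense_train(0, 3600), dense_train(3600 * 2, 3600 * 3),
         dense_train(3600 * 2.2, 3600 * 3.2)),
    list(tmpl, tmpl, tmpl))
  pr <- proposeChainMerges(w$chains, w$centroids, w$snippets)
  from1 <- pr[pr$chainA == 1 & pr$waveformCorr >= 0.9, ]
  expect_gte(nrow(from1), 2L)
  expect_true(all(from1$decision == "flag"))
  merged <- applyChainMerges(w$chains, pr)
  expect_equal(length(merged@chains), 3L)  # nothing auto-merged
})

test_that("gaps beyond the limits suppress acceptance", {
  set.seed(45)
  tmpl <- rnorm(64) * 80
  # 6 h of recording-time gap, no recording gap: beyond the 5 h limit
  w <- make_chain_world(
    list(dense_train(0, 3600), dense_train(3600 * 7, 3600 * 8)),
    list(tmpl, tmpl))
  pr <- proposeChainMerges(w$chains, w$centroids, w$snippets)
  expect_true(all(pr$decision == "reject"))
  # same spacing but bridged by a recording gap: accepted (< 24 h wall)
  gaps <- cbind(start = 3700, end = 3600 * 7 - 60)
  pr2 <- proposeChainMerges(w$chains, w$centroids, w$snippets,
                            recordingGaps = gaps)
  expect_true(any(pr2$decision == "accept"))
})

test_that("low-amplitude chains are flagged for review", {
  set.seed(46)
  tmpl <- rnorm(64) * 10  # well under 100 uV
  w <- make_chain_world(
    list(dense_train(0, 3600), dense_train(3600 * 2, 3600 * 3)),
    list(tmpl, tmpl))
  pr <- proposeChainMerges(w$chains, w$centroids, w$snippets)
  expect_true(all(pr$decision %in% c("flag", "reject")))
})

test_that("decisions are invariant to chain enumeration order", {
  set.seed(47)
  tmpl <- rnorm(64) * 80
  t2 <- rnorm(64) * 80
  w <- make_chain_world(
    list(dense_train(0, 3600), dense_train(3600 * 2, 3600 * 3),
         dense_train(3600 * 4, 3600 * 5)),
    list(tmpl, tmpl, t2))
  pr <- proposeChainMerges(w$chains, w$centroids, w$snippets)
  perm <- c(3L, 1L, 2L)
  cs2 <- new("ChainSet", chains = w$chains@chains[perm],
             unassigned = integer(), nCentroids = w$chains@nCentroids,
             log = w$chains@log)
  pr2 <- proposeChainMerges(cs2, w$centroids, w$snippets)
  key <- function(p, map) {
    d <- p[p$decision == "accept", c("chainA", "chainB")]
    sort(paste(map[d$chainA], map[d$chainB]))
  }
  expect_identical(key(pr, seq_len(3)), key(pr2, perm))
})
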