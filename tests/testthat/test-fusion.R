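test_that("link weight sigmoid hits its anchor points", {
  expect_equal(linkWeight(0.03), 0.5)
  expect_equal(linkWeight(0), 1 / (1 + exp(-6)))
  expect_lt(linkWeight(1), 1e-10)         # d -> infinity limit
  d <- seq(0, 0.2, by = 0.005)
  expect_true(all(diff(linkWeight(d)) < 0))  # strictly decreasing
})

test_that("node quality follows the largest-child path", {
  # chain of identical nodes: 100 -> 100 (leaf)
  labs <- matrix(0L, 2, 100)
  tree <- buildClusterTree(labs)
  expect_equal(nodeQuality(tree, which(tree@depth == 0L)), 0.5)
  leaf <- which(tree@depth == 1L)
  expect_equal(nodeQuality(tree, leaf), 1)
  # splitting path (100, 60, 30)
  lab2 <- rbind(rep(0L, 100), c(rep(0L, 60), rep(1L, 40)),
                c(rep(0L, 30), rep(1L, 30), rep(2L, 40)))
  tree2 <- buildClusterTree(lab2)
  expect_equal(nodeQuality(tree2, which(tree2@depth == 0L)), 100 / 190)
})

test_that("an obvious two-tree unit selects both nodes and the link", {
  prob <- fusionProblem(parents = list(0L, 0L),
                        qualities = list(1, 1),
                        links = list(matrix(0.9, 1, 1)))
  sol <- solveFusionBlock(prob)
  expect_true(sol$exact)
  expect_equal(sol$selected, list(1L, 1L))
  expect_equal(nrow(sol$links), 1L)
  expect_equal(sol$objective, 2 + 0.9 - 0.02)
})

test_that("links below the similarity threshold are never selected", {
  prob <- fusionProblem(parents = list(0L, 0L), qualities = list(1, 1),
                        links = list(matrix(0.01, 1, 1)))
  sol <- solveFusionBlock(prob)
  expect_equal(nrow(sol$links), 0L)
  expect_equal(sol$objective, 2)
})

test_that("solver equals exhaustive enumeration on random small instances", {
  for (s in 1:100) {
    prob <- random_fusion_problem(3, 5, seed = 1000 + s)
    sol <- solveFusionBlock(prob)
    expect_true(sol$exact)
    expect_true(check_fusion_solution(sol, prob))
    expect_equal(sol$objective, fusion_oracle(prob), tolerance = 1e-10)
  }
})

test_that("greedy fallback respects all constraints and warns", {
  prob <- random_fusion_problem(3, 5, seed = 77)
  expect_warning(
    sol <- solveFusionBlock(prob, fusionParams(maxAntichains = 1)),
    "greedy")
  expect_false(sol$exact)
  expect_true(check_fusion_solution(sol, prob))
  expect_lte(sol$objective, fusion_oracle(prob) + 1e-10)
})

test_that("tracking timescale reproduces the worked examples", {
  expect_equal(trackingTimescale(1000 / 16, 8), 2000)
  expect_equal(round(trackingTimescale(1000 / 16, 66)), 242)
  expect_equal(trackingTimescale(1000 / 16, 1), 16000)
  expect_error(trackingTimescale(0, 8), "positive")
})

# ---- stitching and chains on synthetic centroid streams -------------------

# centroid stream: two units drifting slowly, interleaved in time
make_centroid_stream <- function(n_per_tree = 40, n_trees = 4, drift = 0.3,
                                 seed = 31) {
  set.seed(seed)
  d <- 64
  base1 <- rnorm(d) * 30
  base2 <- rnorm(d) * 30
  wf <- NULL
  times <- numeric()
  unit <- integer()
  for (b in seq_len(n_trees * n_per_tree)) {
    u <- (b %% 2) + 1
    base <- if (u == 1) base1 else base2
    wf <- rbind(wf, base + rnorm(d) * 1 + drift * b / n_per_tree)
    times <- c(times, b * 1000)
    unit <- c(unit, u)
  }
  cents <- new("CentroidSet", waveforms = wf, medianTimes = times,
               counts = rep(20L, nrow(wf)), scale = rep(1L, nrow(wf)),
               members = lapply(seq_len(nrow(wf)), function(i)
                 ((i - 1L) * 20L) + 1:20),
               unassigned = integer(), nChannels = 4L,
               samplesPerSpike = 16L)
  list(centroids = cents, unit = unit)
}

test_that("fusion chains separate two drifting units", {
  st <- make_centroid_stream()
  cs <- suppressWarnings(
    fuseCentroids(st$centroids, fusionParams(centroidsPerBlock = 40L),
                  seed = 4))
  expect_gte(length(cs@chains), 2L)
  big <- order(lengths(cs@chains), decreasing = TRUE)[1:2]
  for (ci in big) {
    u <- st$unit[cs@chains[[ci]]]
    expect_gte(max(table(u)) / length(u), 0.95)  # unit-pure chains
  }
  # the two major chains together span most centroids
  expect_gte(sum(lengths(cs@chains[big])), 0.7 * nCentroids(st$centroids))
  expect_true(validObject(cs))
})

test_that("overlap stitching drops links the covering programs disagree on", {
  # two windows over 3 trees with overlap 2: disagreement is constructed by
  # feeding retained-link intersection directly
  links_a <- data.frame(tree = c(1L, 2L), from = c(1L, 1L), to = c(1L, 1L),
                        theta = c(0.9, 0.9))
  links_b <- data.frame(tree = 2L, from = 2L, to = 1L, theta = 0.8)
  nodes <- lapply(1:3, function(i)
    list(members = list(1L + (i - 1L) * 2L, 2L + (i - 1L) * 2L)))
  # both programs agree on tree-1 link, disagree on tree-2 link
  retained <- links_a[1, , drop = FALSE]
  chains <- fastsort:::chain_links(retained, nodes)
  expect_equal(length(chains), 1L)
  expect_equal(chains[[1]], c(1L, 3L))  # chain broke at the disputed link
  # had both agreed, the chain would continue
  both <- rbind(links_a[1, ], links_a[2, ])
  chains2 <- fastsort:::chain_links(both, nodes)
  expect_equal(chains2[[1]], c(1L, 3L, 5L))
})

test_that("orphan centroids join chains only above the straggler threshold", {
  wf <- rbind(matrix(1, 4, 8), matrix(100, 1, 8))
  chains <- list(c(1L, 2L, 3L, 4L))
  got <- fastsort:::attach_stragglers(chains, 5L, wf, scale = 1,
                                      fusionParams())
  expect_equal(got$unassigned, 5L)  # far waveform: theta below threshold
  wf2 <- rbind(matrix(1, 4, 8), matrix(1.001, 1, 8))
  got2 <- fastsort:::attach_stragglers(chains, 5L, wf2, scale = 1,
                                       fusionParams())
  expect_equal(length(got2$unassigned), 0L)
  expect_true(5L %in% got2$chains[[1]])
})

test_that("translation-invariant merge joins shifted duplicates only", {
  set.seed(32)
  d <- 64
  n_ch <- 4L
  sps <- 16L
  base <- as.vector(outer(c(1, .5, .3, .2),
                          150 * exp(-((1:16 - 8) / 2)^2)))
  m <- matrix(base, n_ch, sps, byrow = FALSE)  # channels x samples
  vec0 <- as.vector(t(m))
  shift5 <- as.vector(t(cbind(m[, 6:16], matrix(0, 4, 5))))
  orth <- as.vector(t(rbind(m[4:1, ])))  # different channel profile
  wf <- rbind(vec0, shift5, orth, vec0)
  cents <- new("CentroidSet", waveforms = wf,
               medianTimes = c(100, 200, 250, 300),
               counts = rep(20L, 4), scale = rep(1L, 4),
               members = lapply(0:3, function(i) i * 20L + 1:20),
               unassigned = integer(), nChannels = n_ch,
               samplesPerSpike = sps)
  cs <- new("ChainSet",
            chains = list(c(1L, 4L), 2L, 3L), unassigned = integer(),
            nCentroids = 4L, log = list(distScale = 0.001))
  merged <- mergeTranslationInvariant(cs, cents, fusionParams())
  ch <- merged@chains
  # the shifted copy merged with the original; the orthogonal one did not
  home <- which(vapply(ch, function(c) 1L %in% c, TRUE))
  expect_true(2L %in% ch[[home]])
  expect_false(3L %in% ch[[home]])
})

test_that("chain merging is order-independent for non-interacting pairs", {
  st <- make_centroid_stream(seed = 33)
  cs <- suppressWarnings(
    fuseCentroids(st$centroids, fusionParams(centroidsPerBlock = 40L),
                  seed = 4, mergeChains = FALSE))
  m1 <- mergeTranslationInvariant(cs, st$centroids, fusionParams())
  perm <- rev(seq_along(cs@chains))
  cs2 <- new("ChainSet", chains = cs@chains[perm],
             unassigned = cs@unassigned, nCentroids = cs@nCentroids,
             log = cs@log)
  m2 <- mergeTranslationInvariant(cs2, st$centroids, fusionParams())
  norm <- function(m) canon_partition(m@chains)
  expect_identical(norm(m1), norm(m2))
})
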