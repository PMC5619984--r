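test_that("collapse keeps two well-separated clouds apart", {
  cl <- make_clouds(c(60, 40), sep = 20, d = 64, seed = 21)
  # hand-built tree: root splits into the two clouds, then leaves
  labs <- rbind(rep(0L, 100), cl$labels - 1L, cl$labels - 1L)
  tree <- buildClusterTree(labs)
  parts <- collapseTree(tree, cl$x, collapseParams(dof = 64))
  expect_equal(length(parts), 2L)
  expect_identical(canon_partition(parts),
                   canon_partition(split(seq_len(100), cl$labels)))
})

test_that("identical points collapse into a single cluster", {
  # identical points never separate in the sweep: constant labels
  x <- matrix(5, 40, 32)
  labs <- matrix(0L, 4, 40)
  tree <- buildClusterTree(labs)
  parts <- collapseTree(tree, x, collapseParams(dof = 32))
  expect_equal(length(parts), 1L)
  expect_equal(parts[[1]], 1:40)
  # and a split of identical points is healed (a_L = 0 everywhere)
  labs2 <- rbind(rep(0L, 40), rep(0L, 40), rep(0:3, each = 10))
  parts2 <- collapseTree(buildClusterTree(labs2), x, collapseParams(dof = 32))
  expect_equal(length(parts2), 1L)
})

test_that("collapse equals the straight-line oracle on random trees", {
  for (s in 1:100) {
    set.seed(400 + s)
    n <- sample(20:40, 1)
    d <- 16
    # mixture of a few blobs with modest separation so both regimes occur
    k <- sample(2:4, 1)
    mu <- matrix(rnorm(k * d, sd = sample(c(2, 8, 20), 1)), k, d)
    z <- sample.int(k, n, replace = TRUE)
    x <- mu[z, ] + matrix(rnorm(n * d), n, d)
    labs <- random_labels(n, sample(3:5, 1), max_k = 3, seed = 500 + s)
    tree <- buildClusterTree(labs)
    params <- collapseParams(dof = d, mergeThreshold = sample(c(1, 3, 10), 1))
    got <- canon_partition(collapseTree(tree, x, params))
    want <- canon_partition(collapse_oracle(tree, x,
                                            a = params@mergeThreshold, nu = d))
    expect_identical(got, want)
  }
})

test_that("clusterBlock emits centroids only for clusters of >= 15 spikes", {
  cl <- make_clouds(c(700, 300), sep = 25, seed = 22)
  res <- clusterBlock(cl$x, seq_len(1000), collapseParams(), seed = 31)
  expect_equal(length(res$centroids), 2L)
  sizes <- sort(vapply(res$centroids, `[[`, 0L, "count"), decreasing = TRUE)
  expect_gte(sizes[1], 650)
  expect_gte(sizes[2], 250)
  expect_lte(length(res$leftover), 50)
  # centroid equals the arithmetic mean of its members
  ce <- res$centroids[[1]]
  expect_equal(ce$waveform, colMeans(cl$x[ce$members, ]))
})

test_that("a block of identical snippets yields one centroid", {
  x <- matrix(3, 100, 64)
  res <- clusterBlock(x, seq_len(100), collapseParams(dof = 64))
  expect_equal(length(res$centroids), 1L)
  expect_equal(res$centroids[[1]]$count, 100L)
  expect_equal(res$centroids[[1]]$waveform, rep(3, 64))
})

test_that("blocks below the minimum cluster size go entirely to leftovers", {
  # 1000 spikes from 100 equal-rate clusters of 10: none reaches 15 members
  set.seed(23)
  mu <- matrix(rnorm(100 * 32, sd = 40), 100, 32)
  x <- mu[rep(1:100, each = 10), ] + matrix(rnorm(1000 * 32, sd = 0.1), 1000, 32)
  res <- clusterBlock(x, seq_len(1000), collapseParams(dof = 32), seed = 5)
  expect_equal(length(res$centroids), 0L)
  expect_equal(sort(res$leftover), 1:1000)
})

test_that("multi-scale clustering recovers slow units at later scales", {
  # fast unit dominates every 1000-spike block; the slow unit never reaches
  # 15 spikes per block at scale 1 and must be recovered after re-pooling;
  # diffuse noise events supply the rest of the leftover pool
  set.seed(24)
  n_fast <- 6000
  n_slow <- 60
  n_noise <- 300
  d <- 64
  fast <- matrix(rnorm(n_fast * d), n_fast, d) + 50
  slow <- matrix(rnorm(n_slow * d), n_slow, d) - 50
  noise <- matrix(rnorm(n_noise * d, sd = 30), n_noise, d)
  n <- n_fast + n_slow + n_noise
  lab <- rep(1:3, c(n_fast, n_slow, n_noise))
  ord <- sample(n)   # interleave in time
  x <- rbind(fast, slow, noise)[ord, ]
  lab <- lab[ord]
  times <- sort(sample.int(3e6, n))
  cents <- multiscaleCluster(x, collapseParams(dof = d), times = times,
                             seed = 7)
  slow_cent <- which(vapply(seq_len(nCentroids(cents)), function(i)
    mean(lab[cents@members[[i]]] == 2) > 0.5, TRUE))
  fast_cent <- which(vapply(seq_len(nCentroids(cents)), function(i)
    mean(lab[cents@members[[i]]] == 1) > 0.5, TRUE))
  expect_gte(length(slow_cent), 1L)
  expect_equal(min(cents@scale[fast_cent]), 1L)  # fast unit found at scale 1
  expect_gte(min(cents@scale[slow_cent]), 2L)    # slow unit appears later
  # >= 95% of the slow unit's spikes assigned by scale 4
  assigned_slow <- sum(lab[unlist(cents@members[slow_cent])] == 2)
  expect_gte(assigned_slow / n_slow, 0.95)
})

test_that("empty input produces an empty centroid set", {
  cents <- multiscaleCluster(matrix(0, 0, 256), times = numeric())
  expect_equal(nCentroids(cents), 0L)
  expect_equal(length(cents@unassigned), 0L)
})

test_that("conservation: members plus unassigned account for every snippet", {
  cl <- make_clouds(c(900, 700, 150), sep = 25, seed = 25)
  ord <- sample(nrow(cl$x))
  cents <- multiscaleCluster(cl$x[ord, ], times = sort(sample.int(1e6, 1750)),
                             seed = 8)
  got <- sort(c(unlist(cents@members), cents@unassigned))
  expect_equal(got, 1:1750)
  expect_true(validObject(cents))
  # assignment fraction high for well-separated clusters
  expect_gte(sum(cents@counts) / 1750, 0.95)
})
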