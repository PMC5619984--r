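test_that("two well-separated clouds are recovered at some temperature", {
  cl <- make_clouds(c(500, 500), sep = 20, seed = 11)
  lab <- runSpcSweep(cl$x, seed = 1)
  agree <- apply(lab, 1, function(r) {
    if (length(unique(r)) != 2) return(0)
    tab <- table(r, cl$labels)
    sum(apply(tab, 1, max)) / length(cl$labels)
  })
  expect_gte(max(agree), 0.99)
  # at t = 0 all points share one label
  expect_equal(length(unique(lab[1, ])), 1L)
})

test_that("identical points form one cluster at every temperature", {
  x <- matrix(1, 50, 32)
  lab <- runSpcSweep(x, seed = 2)
  expect_true(all(apply(lab, 1, function(r) length(unique(r))) == 1L))
})

test_that("three clouds (400/400/200) are recovered with >= 95% agreement", {
  cl <- make_clouds(c(400, 400, 200), sep = 25, seed = 12)
  lab <- runSpcSweep(cl$x, seed = 3)
  # adjusted-Rand-style agreement: best temperature with exactly 3 clusters
  agree <- apply(lab, 1, function(r) {
    if (length(unique(r)) != 3) return(0)
    tab <- table(r, cl$labels)
    sum(apply(tab, 1, max)) / length(cl$labels)
  })
  expect_gte(max(agree), 0.95)
})

test_that("sweep is deterministic given a seed", {
  cl <- make_clouds(c(60, 60), sep = 10, d = 32, seed = 13)
  l1 <- runSpcSweep(cl$x, seed = 9)
  l2 <- runSpcSweep(cl$x, seed = 9)
  expect_identical(l1, l2)
})

test_that("tiny inputs return a single cluster with a warning", {
  x <- matrix(rnorm(10 * 8), 10, 8)
  expect_warning(lab <- runSpcSweep(x), "single cluster")
  expect_true(all(lab == 0L))
})

test_that("cluster trees are built from labels with enforced nesting", {
  labs <- rbind(rep(0L, 4), c(0L, 0L, 1L, 1L))
  tree <- buildClusterTree(labs, temperatures = c(0, 0.01))
  expect_equal(length(tree@members), 3L)
  root <- which(tree@depth == 0L)
  expect_equal(tree@members[[root]], 1:4)
  kids <- tree@children[[root]]
  expect_equal(unname(sort(lengths(tree@members[kids]))), c(2L, 2L))
  # constant labels produce a chain of single-child nodes
  labs2 <- matrix(0L, 5, 6)
  tree2 <- buildClusterTree(labs2)
  expect_equal(max(tree2@depth), 4L)
  expect_true(all(lengths(tree2@members) == 6L))
})

test_that("every node's children partition it on random nested labels", {
  for (s in 1:5) {
    labs <- random_labels(50, 5, seed = 100 + s)
    tree <- buildClusterTree(labs)
    expect_true(validObject(tree))  # validity checks the partition property
    # sum of leaf sizes equals n
    expect_equal(sum(lengths(tree@members[treeLeaves(tree)])), 50L)
  }
})

test_that("agglomerative fallback refines hierarchically over the grid", {
  cl <- make_clouds(c(40, 40), sep = 15, d = 16, seed = 14)
  lab <- runSpcSweep(cl$x, method = "agglomerative")
  k <- unname(apply(lab, 1, function(r) length(unique(r))))
  expect_equal(k[1], 1L)
  expect_true(all(diff(k) >= 0))
})
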