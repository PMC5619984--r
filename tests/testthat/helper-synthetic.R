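# shared fixtures, built in code

# well-separated Gaussian clouds in d dimensions; returns waveforms + labels
make_clouds <- function(sizes, sep = 20, d = 256, sd = 1, seed = 1) {
  set.seed(seed)
  centers <- matrix(0, length(sizes), d)
  for (k in seq_along(sizes)) centers[k, k] <- sep * sd * (k - 1) + sep * sd
  x <- do.call(rbind, lapply(seq_along(sizes), function(k)
    matrix(rnorm(sizes[k] * d, sd = sd), sizes[k], d) +
      matrix(centers[k, ], sizes[k], d, byrow = TRUE)))
  list(x = x, labels = rep(seq_along(sizes), sizes))
}

# hand-built SpcTree from a label matrix (temperatures x points)
tree_from_labels <- function(labels) buildClusterTree(labels)

# independent straight-line implementation of the recursive tree collapse:
# computes d_L and d_P by explicit summation over points (no algebraic
# shortcuts) and applies the written merge rules level by level
collapse_oracle <- function(tree, x, a = 20, nu = 256) {
  loss <- function(pts, centroid)
    sum(vapply(pts, function(i) sum((x[i, ] - centroid)^2), 0))
  leaves <- lapply(which(tree@depth == max(tree@depth)), function(i)
    list(members = tree@members[[i]], parent = tree@parent[i]))
  d <- max(tree@depth)
  while (d >= 2) {
    groups <- split(leaves, vapply(leaves, `[[`, 0L, "parent"))
    leaves <- list()
    for (grp in groups) {
      p_node <- grp[[1]]$parent
      mem <- lapply(grp, `[[`, "members")
      all_pts <- unlist(mem)
      p_cent <- colMeans(x[all_pts, , drop = FALSE])
      cents <- lapply(mem, function(m) colMeans(x[m, , drop = FALSE]))
      aL <- numeric(length(mem))
      for (i in seq_along(mem)) {
        dL <- loss(mem[[i]], cents[[i]])
        dP <- loss(mem[[i]], p_cent)
        aL[i] <- sqrt((dP - dL) / nu)
      }
      iso <- which(aL > a)
      if (length(iso) == 0) {
        new_nodes <- list(all_pts)
      } else {
        new_nodes <- mem[iso]
        rest <- integer()
        for (i in setdiff(seq_along(mem), iso)) {
          dLi <- loss(mem[[i]], cents[[i]])
          ex <- vapply(iso, function(j)
            sqrt((loss(mem[[i]], cents[[j]]) - dLi) / nu), 0)
          if (min(ex) < a) {
            tgt <- which.min(ex)
            new_nodes[[tgt]] <- c(new_nodes[[tgt]], mem[[i]])
          } else {
            rest <- c(rest, mem[[i]])
          }
        }
        if (length(rest)) new_nodes <- c(new_nodes, list(rest))
      }
      gp <- tree@parent[p_node]
      for (m in new_nodes)
        leaves[[length(leaves) + 1L]] <- list(members = m, parent = gp)
    }
    d <- d - 1
  }
  parts <- lapply(leaves, function(l) sort(l$members))
  parts[order(vapply(parts, min, 0))]
}

# canonical form of a partition for comparison
canon_partition <- function(parts) {
  parts <- lapply(parts, function(p) as.integer(sort(unname(p))))
  unname(parts[order(vapply(parts, min, 0L))])
}

# random uniform-depth label matrices for property tests
random_labels <- function(n, n_temps, max_k = 4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  labs <- matrix(0L, n_temps, n)
  for (d in 2:n_temps)
    labs[d, ] <- sample.int(max_k, n, replace = TRUE) - 1L
  labs
}

# random fusion-problem instance over small random trees
random_fusion_problem <- function(n_trees = 3, max_nodes = 5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ns <- sample(2:max_nodes, n_trees, replace = TRUE)
  parents <- lapply(ns, function(n) {
    p <- integer(n)
    if (n > 1) for (i in 2:n) p[i] <- sample.int(i - 1, 1)
    p
  })
  quals <- lapply(ns, function(n) runif(n, 0.05, 1))
  links <- lapply(seq_len(n_trees - 1), function(i)
    matrix(runif(ns[i] * ns[i + 1]), ns[i], ns[i + 1]))
  fusionProblem(parents, quals, links)
}

# exhaustive fusion oracle: enumerate every feasible assignment (all
# antichain combinations x all feasible link matchings) and return the best
# objective
fusion_oracle <- function(prob) {
  ac <- lapply(prob$parents, fastsort:::enumerate_antichains)
  nt <- length(ac)
  best_matching <- function(w, s1, s2) {
    best <- 0
    rec <- function(i, used2, val) {
      if (i > length(s1)) {
        best <<- max(best, val)
        return(invisible())
      }
      rec(i + 1, used2, val)
      for (j in seq_along(s2)) if (!used2[j]) {
        u <- used2
        u[j] <- TRUE
        rec(i + 1, u, val + w[s1[i], s2[j]] - prob$linkThreshold)
      }
    }
    rec(1, logical(length(s2)), 0)
    best
  }
  grid <- expand.grid(lapply(ac, seq_along))
  best <- -Inf
  for (r in seq_len(nrow(grid))) {
    sel <- lapply(seq_len(nt), function(i) ac[[i]][[grid[r, i]]])
    v <- sum(vapply(seq_len(nt), function(i)
      sum(prob$qualities[[i]][sel[[i]]]), 0))
    for (i in seq_len(nt - 1))
      if (length(sel[[i]]) && length(sel[[i + 1]]))
        v <- v + best_matching(prob$links[[i]], sel[[i]], sel[[i + 1]])
    if (v > best) best <- v
  }
  best
}

# verify a fusion solution against every constraint of the binary program
check_fusion_solution <- function(sol, prob) {
  nt <- length(prob$parents)
  for (i in seq_len(nt)) {
    sel <- sol$selected[[i]]
    # path exclusivity: no selected node may be an ancestor of another
    for (v in sel) {
      p <- prob$parents[[i]][v]
      while (p > 0) {
        if (p %in% sel) return(FALSE)
        p <- prob$parents[[i]][p]
      }
    }
  }
  lk <- sol$links
  if (nrow(lk)) {
    for (r in seq_len(nrow(lk))) {
      if (!(lk$from[r] %in% sol$selected[[lk$tree[r]]])) return(FALSE)
      if (!(lk$to[r] %in% sol$selected[[lk$tree[r] + 1]])) return(FALSE)
      if (lk$theta[r] < prob$linkThreshold) return(FALSE)
    }
    if (anyDuplicated(paste(lk$tree, lk$from))) return(FALSE)
    if (anyDuplicated(paste(lk$tree + 1, lk$to))) return(FALSE)
  }
  TRUE
}
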