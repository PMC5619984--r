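#' Collapse a cluster tree into a partition (loss-compression rule)
#'
#' Recursively collapses the deepest level of the tree into its parents, one
#' level at a time, until the tree has depth 1; the surviving depth-1 nodes
#' partition the block. For each parent with leaves L_1..L_N the per-leaf
#' loss excess is a_L = sqrt((d_P - d_L) / nu) -- the root-mean-square
#' per-degree-of-freedom extra loss, in uV, incurred by approximating the
#' leaf's points with the parent centroid instead of the leaf centroid (d_L
#' is the summed squared distance of the leaf's points to the leaf centroid
#' and d_P to the parent centroid). Leaves with a_L > a (the merge threshold,
#' a distance in uV) are well isolated and survive; each remaining leaf
#' merges into the well-isolated leaf that approximates it within a (smallest
#' excess loss), if any, and all leftover leaves merge with each other into a
#' single node.
#'
#' @param tree an \code{\linkS4class{SpcTree}} of the block.
#' @param x numeric matrix of the block's waveforms (points in rows), uV.
#' @param params a \code{CollapseParams} (uses \code{mergeThreshold} and
#'   \code{dof}).
#' @return list of integer vectors partitioning \code{seq_len(nrow(x))}.
#' @export
collapseTree <- function(tree, x, params = collapseParams()) {
  a <- params@mergeThreshold
  nu <- params@dof
  maxd <- max(tree@depth)
  if (maxd == 0L) return(list(seq_len(tree@nPoints)))
  # leaves at the deepest level, keyed by original-tree parent
  leaves <- lapply(which(tree@depth == maxd), function(i)
    list(members = tree@members[[i]], parent = tree@parent[i]))
  for (d in (if (maxd >= 2L) seq(maxd, 2L) else integer())) {
    by_parent <- split(leaves, vapply(leaves, `[[`, 0L, "parent"))
    leaves <- list()
    for (grp in by_parent) {
      p_node <- grp[[1]]$parent
      merged <- collapse_siblings(lapply(grp, `[[`, "members"), x, a, nu)
      gp <- tree@parent[p_node]
      for (m in merged)
        leaves[[length(leaves) + 1L]] <- list(members = m, parent = gp)
    }
  }
  lapply(leaves, function(l) sort(l$members))
}

# One collapse step: merge a set of sibling leaves (lists of point indices)
# under a common parent per the loss-compression rule. Uses the identity
# sum ||x - c||^2 = d_L + N * ||l - c||^2 to avoid re-summing over points.
collapse_siblings <- function(member_list, x, a, nu) {
  nL <- length(member_list)
  if (nL == 1L) return(member_list)
  cents <- lapply(member_list, function(m)
    colMeans(x[m, , drop = FALSE]))
  sizes <- lengths(member_list)
  p_members <- unlist(member_list, use.names = FALSE)
  p_cent <- colMeans(x[p_members, , drop = FALSE])
  a_L <- vapply(seq_len(nL), function(i)
    sqrt(sizes[i] * sum((cents[[i]] - p_cent)^2) / nu), 0)
  iso <- which(a_L > a)
  if (!length(iso)) return(list(sort(p_members)))
  groups <- as.list(member_list[iso])
  leftovers <- integer()
  for (i in setdiff(seq_len(nL), iso)) {
    excess <- vapply(iso, function(j)
      sqrt(sizes[i] * sum((cents[[i]] - cents[[j]])^2) / nu), 0)
    if (min(excess) < a) {
      tgt <- which.min(excess)
      groups[[tgt]] <- c(groups[[tgt]], member_list[[i]])
    } else {
      leftovers <- c(leftovers, member_list[[i]])
    }
  }
  out <- lapply(groups, sort)
  if (length(leftovers)) out <- c(out, list(sort(leftovers)))
  out
}

#' Locally cluster one block of snippets
#'
#' Runs the SPC temperature sweep on a block of consecutive snippets, builds
#' the cluster tree, collapses it, and emits the centroid (arithmetic mean
#' waveform) of every cluster with at least \code{minClusterSize} members.
#' Snippets in smaller clusters form the leftover pool.
#'
#' @param x numeric matrix [snippets x features] of the block, uV.
#' @param times numeric, peak times of the block's snippets (samples).
#' @param params a \code{CollapseParams}.
#' @param method clustering engine passed to \code{\link{runSpcSweep}}.
#' @param ... further arguments to \code{\link{runSpcSweep}}.
#' @return list with \code{centroids} (a list of
#'   \code{list(waveform, medianTime, count, members)}, members as indices
#'   into the block) and \code{leftover} (block indices).
#' @export
clusterBlock <- function(x, times, params = collapseParams(),
                         method = "spc", ...) {
  n <- nrow(x)
  if (n < params@minSpcSize)
    return(list(centroids = list(), leftover = seq_len(n)))
  labels <- suppressWarnings(
    runSpcSweep(x, tMin = 0, tMax = params@tMax, tStep = params@tStep,
                method = method, ...))
  tree <- buildClusterTree(labels)
  parts <- collapseTree(tree, x, params)
  centroids <- list()
  leftover <- integer()
  for (p in parts) {
    if (length(p) >= params@minClusterSize) {
      centroids[[length(centroids) + 1L]] <- list(
        waveform = colMeans(x[p, , drop = FALSE]),
        medianTime = stats::median(times[p]),
        count = length(p), members = p)
    } else {
      leftover <- c(leftover, p)
    }
  }
  list(centroids = centroids, leftover = sort(leftover))
}

#' Multi-scale local clustering of a snippet store (Step 1)
#'
#' Compresses N snippets into roughly N/100 de-noised centroid waveforms.
#' Snippets are clustered in blocks of \code{blockSize} consecutive events;
#' clusters with at least \code{minClusterSize} members emit a centroid, and
#' all remaining snippets are pooled, kept in time order, re-blocked and
#' re-clustered at the next scale. This repeats for \code{nScales} rounds so
#' that units too slow to reach \code{minClusterSize} spikes within one block
#' at an early scale are recovered at a later, temporally coarser one. A
#' trailing partial block is clustered as-is when it has at least
#' \code{minPartialBlock} snippets and otherwise carried to the next scale.
#'
#' @param snippets a \code{SnippetSet}, or a numeric waveform matrix (then
#'   \code{times} must be given).
#' @param params a \code{CollapseParams}.
#' @param seed integer seed for the SPC sweeps.
#' @param times peak times when \code{snippets} is a bare matrix.
#' @param method,... passed to \code{\link{runSpcSweep}}.
#' @param verbose print per-scale progress.
#' @return A \code{\linkS4class{CentroidSet}}; the assignment fraction is
#'   \code{sum(counts) / nrow(snippets)}.
#' @export
multiscaleCluster <- function(snippets, params = collapseParams(), seed = NULL,
                              times = NULL, method = "spc", verbose = FALSE,
                              ...) {
  if (is(snippets, "SnippetSet")) {
    x <- waveforms(snippets)
    times <- peakTimes(snippets)
    n_ch <- snippets@nChannels
    sps <- snippets@samplesPerSpike
  } else {
    x <- as.matrix(snippets)
    if (is.null(times)) stop("times required for matrix input")
    n_ch <- 4L
    sps <- as.integer(ncol(x) / 4L)
  }
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  n <- nrow(x)
  pool <- seq_len(n)
  cents <- list()
  for (scale in seq_len(params@nScales)) {
    if (!length(pool)) break
    starts <- seq(1L, length(pool), by = params@blockSize)
    next_pool <- integer()
    n_blocks <- 0L
    for (b0 in starts) {
      b1 <- min(b0 + params@blockSize - 1L, length(pool))
      idx <- pool[b0:b1]
      if (length(idx) < params@blockSize &&
          length(idx) < params@minPartialBlock && b0 > 1L) {
        next_pool <- c(next_pool, idx)  # carry trailing sliver to next scale
        next
      }
      res <- clusterBlock(x[idx, , drop = FALSE], times[idx], params,
                          method = method, ...)
      n_blocks <- n_blocks + 1L
      for (ce in res$centroids) {
        ce$members <- idx[ce$members]
        ce$scale <- scale
        cents[[length(cents) + 1L]] <- ce
      }
      next_pool <- c(next_pool, idx[res$leftover])
    }
    if (verbose)
      message(sprintf("scale %d: %d block(s), %d centroid(s), %d leftover",
                      scale, n_blocks, length(cents), length(next_pool)))
    pool <- sort(next_pool)
  }
  ord <- order(vapply(cents, `[[`, 0, "medianTime"))
  cents <- cents[ord]
  wf <- if (length(cents))
    do.call(rbind, lapply(cents, `[[`, "waveform")) else matrix(0, 0, ncol(x))
  new("CentroidSet",
      waveforms = wf,
      medianTimes = vapply(cents, `[[`, 0, "medianTime"),
      counts = as.integer(vapply(cents, `[[`, 0L, "count")),
      scale = as.integer(vapply(cents, `[[`, 0L, "scale")),
      members = lapply(cents, `[[`, "members"),
      unassigned = as.integer(pool),
      nChannels = n_ch, samplesPerSpike = as.integer(sps))
}
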