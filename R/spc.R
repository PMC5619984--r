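#' Superparamagnetic clustering temperature sweep
#'
#' Clusters waveform vectors with a q-state Potts model over a grid of
#' temperatures: at each temperature, Swendsen-Wang Monte Carlo estimates the
#' spin-spin correlation of neighbouring points (mutual K-nearest-neighbour
#' graph augmented with the Euclidean minimum spanning tree, so the graph is
#' connected), and points whose correlation exceeds \code{corrThreshold} share
#' a cluster. At temperature 0 all points share one label; increasing the
#' temperature refines the partition. Distances are plain Euclidean in the raw
#' input space. A deterministic agglomerative mode (single-linkage with
#' distance cutoffs mapped to the temperature grid) is available for fast
#' tests.
#'
#' @param x numeric matrix, one point per row (e.g. snippets x 256).
#' @param tMin,tMax,tStep temperature grid \code{seq(tMin, tMax, tStep)}.
#' @param seed integer seed; when non-NULL the sweep is reproducible.
#' @param q Potts spin states.
#' @param K mutual nearest-neighbour count.
#' @param sweeps,burnin Monte-Carlo sweeps measured / discarded per
#'   temperature.
#' @param corrThreshold spin-correlation threshold joining points.
#' @param minPoints below this many points the sweep is skipped and a
#'   single-cluster labelling is returned with a warning.
#' @param method \code{"spc"} (default) or \code{"agglomerative"}.
#' @return integer matrix [temperatures x points] of 0-based cluster labels,
#'   with temperatures as row names.
#' @export
runSpcSweep <- function(x, tMin = 0, tMax = 0.15, tStep = 0.01, seed = NULL,
                        q = 20, K = 11, sweeps = 250, burnin = 50,
                        corrThreshold = 0.5, minPoints = 20,
                        method = c("spc", "agglomerative")) {
  method <- match.arg(method)
  x <- as.matrix(x)
  n <- nrow(x)
  temps <- seq(tMin, tMax, by = tStep)
  if (n < minPoints) {
    warning("fewer than ", minPoints, " points; returning a single cluster")
    labels <- matrix(0L, length(temps), n)
    rownames(labels) <- format(temps)
    return(labels)
  }
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  if (method == "spc") {
    d <- cpp_pairwise_dist(x)
    labels <- cpp_spc_sweep(d, temps, as.integer(q), as.integer(K),
                            as.integer(sweeps), as.integer(burnin),
                            corrThreshold)
  } else {
    d <- stats::dist(x)
    hc <- stats::hclust(d, method = "single")
    hmax <- max(hc$height)
    labels <- matrix(0L, length(temps), n)
    for (i in seq_along(temps)) {
      h <- hmax * (1 - temps[i] / (max(temps) + tStep))
      labels[i, ] <- as.integer(stats::cutree(hc, h = max(h, 0))) - 1L
    }
  }
  rownames(labels) <- format(temps)
  labels
}

#' Build a cluster tree from a temperature-sweep label matrix
#'
#' Converts per-temperature cluster labels into a tree whose root (depth 0)
#' contains all points and whose depth-d nodes partition their parents
#' according to the labels at the d-th temperature. Non-nested labels (possible
#' with Monte-Carlo noise) are resolved by intersecting each temperature's
#' clusters with the parent partition, so children always partition their
#' parent. Every root-to-leaf path has length equal to the number of
#' temperature increments.
#'
#' @param labels integer matrix [temperatures x points] from
#'   \code{\link{runSpcSweep}}.
#' @param temperatures the temperature grid (defaults to the label row names).
#' @return An \code{\linkS4class{SpcTree}}.
#' @export
buildClusterTree <- function(labels, temperatures = NULL) {
  stopifnot(is.matrix(labels), nrow(labels) >= 1)
  n <- ncol(labels)
  if (is.null(temperatures)) {
    temperatures <- suppressWarnings(as.numeric(rownames(labels)))
    if (anyNA(temperatures)) temperatures <- seq_len(nrow(labels)) - 1
  }
  members <- list(seq_len(n))
  depth <- 0L
  parent <- 0L
  group <- rep(1L, n)  # node index of each point at the current depth
  for (d in seq_len(nrow(labels) - 1L)) {
    # nest this temperature's labels inside the current partition
    key <- group * (max(labels[d + 1L, ]) + 1L) + labels[d + 1L, ]
    new_group <- match(key, sort(unique(key)))
    parts <- split(seq_len(n), new_group)
    base <- length(members)
    members <- c(members, parts)
    depth <- c(depth, rep.int(d, length(parts)))
    parent <- c(parent, vapply(parts, function(p) group[p[1]], 0L))
    group <- base + new_group
  }
  children <- vector("list", length(members))
  for (i in seq_along(members)) children[[i]] <- integer()
  for (i in which(parent > 0L))
    children[[parent[i]]] <- c(children[[parent[i]]], i)
  new("SpcTree", nPoints = as.integer(n), temperatures = temperatures,
      members = lapply(members, as.integer), depth = as.integer(depth),
      parent = as.integer(parent), children = children)
}

#' Leaf nodes of a cluster tree
#' @param tree an \code{SpcTree}.
#' @return integer vector of node indices with no children.
#' @export
treeLeaves <- function(tree) which(lengths(tree@children) == 0L)
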