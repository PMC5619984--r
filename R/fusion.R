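#' Link-weight sigmoid
#'
#' Maps a (normalised) Euclidean distance d between node mean waveforms to a
#' similarity theta = a / (1 + a), a = exp(-(d - k) / s), strictly decreasing
#' in d with theta = 0.5 at d = k.
#'
#' @param d non-negative distance(s).
#' @param s sigmoid steepness (default 0.005).
#' @param k distance of half similarity (default 0.03).
#' @return similarity in (0, 1).
#' @export
linkWeight <- function(d, s = 0.005, k = 0.03) {
  stopifnot(all(d >= 0))
  stats::plogis((k - d) / s)
}

#' Node quality of a cluster-tree node
#'
#' Following the largest-child path from the node down to a leaf gives sizes
#' N(0), N(1), ..., N(a); the quality is N(0) / (N(0) + ... + N(a)). It
#' penalises clusters that split into smaller clusters at higher temperatures
#' and clusters that appear only at high temperatures; a leaf has quality 1.
#'
#' @param tree an \code{\linkS4class{SpcTree}}.
#' @param node node index.
#' @return quality in (0, 1].
#' @export
nodeQuality <- function(tree, node) {
  sizes <- length(tree@members[[node]])
  v <- node
  repeat {
    kids <- tree@children[[v]]
    if (!length(kids)) break
    ks <- lengths(tree@members[kids])
    v <- kids[which.max(ks)]
    sizes <- c(sizes, max(ks))
  }
  sizes[1] / sum(sizes)
}

#' Segmentation-fusion problem
#'
#' A binary linear program over node variables (one per cluster-tree node,
#' weighted by node quality) and link variables (one per node pair in adjacent
#' trees, weighted by waveform similarity). Constraints: at most one node per
#' root-to-leaf path of each tree; at most one chosen outgoing and one chosen
#' incoming link per chosen node; links require both end nodes. The objective
#' is sum(C * quality) + sum(L * (theta - linkThreshold)).
#'
#' @param parents list (one per tree) of parent-index vectors (0 = root).
#' @param qualities list of node-quality vectors, values in (0, 1].
#' @param links list (one per adjacent tree pair) of similarity matrices
#'   theta in (0, 1), dimensions nodes(i) x nodes(i + 1).
#' @param members optional list of per-tree lists of member centroid ids.
#' @param linkThreshold similarity below which links are never selected.
#' @return An object of class \code{FusionProblem}.
#' @export
fusionProblem <- function(parents, qualities, links, members = NULL,
                          linkThreshold = 0.02) {
  stopifnot(length(parents) == length(qualities),
            length(links) == length(parents) - 1L)
  for (i in seq_along(links)) {
    stopifnot(nrow(links[[i]]) == length(qualities[[i]]),
              ncol(links[[i]]) == length(qualities[[i + 1L]]))
    if (any(links[[i]] <= 0) || any(links[[i]] >= 1))
      stop("link similarities must lie in (0, 1)")
  }
  structure(list(parents = parents, qualities = qualities, links = links,
                 members = members, linkThreshold = linkThreshold),
            class = "FusionProblem")
}

children_of <- function(parent) {
  kids <- vector("list", length(parent))
  for (i in seq_along(parent))
    if (parent[i] > 0L) kids[[parent[i]]] <- c(kids[[parent[i]]], i)
  kids
}

count_antichains <- function(parent) {
  kids <- children_of(parent)
  root <- which(parent == 0L)
  cnt <- function(v) {
    if (!length(kids[[v]])) return(2)
    prod(vapply(kids[[v]], cnt, 0)) + 1
  }
  sum(vapply(root, cnt, 0)) - (length(root) - 1)  # single root in practice
}

enumerate_antichains <- function(parent, cap = Inf) {
  kids <- children_of(parent)
  root <- which(parent == 0L)
  rec <- function(v) {
    below <- list(integer())
    for (c in kids[[v]]) {
      cc <- rec(c)
      below <- unlist(lapply(below, function(b)
        lapply(cc, function(s) c(b, s))), recursive = FALSE)
      if (length(below) > cap) stop("antichain cap exceeded")
    }
    c(list(as.integer(v)), below)
  }
  out <- rec(root[1])
  if (length(out) > cap) stop("antichain cap exceeded")
  out
}

max_antichain_size <- function(parent) {
  kids <- children_of(parent)
  root <- which(parent == 0L)
  rec <- function(v) {
    if (!length(kids[[v]])) return(1L)
    max(1L, sum(vapply(kids[[v]], rec, 0L)))
  }
  rec(root[1])
}

#' Solve one segmentation-fusion block
#'
#' Finds the optimal feasible assignment of the fusion binary program. The
#' path-exclusivity constraints make the per-tree feasible node selections
#' exactly the antichains of each tree, and because links only join adjacent
#' trees the problem decomposes as a chain: dynamic programming over per-tree
#' antichain choices with exact max-weight bipartite matching between the
#' selected node sets of adjacent trees yields the global optimum. When the
#' antichain enumeration exceeds \code{maxAntichains} per tree (or the total
#' matching work exceeds \code{maxExactWork}), a greedy fallback is used
#' (per-tree maximum-quality antichain, then links accepted in descending
#' similarity while respecting all constraints) and a warning records that
#' optimality is no longer guaranteed.
#'
#' @param problem a \code{\link{fusionProblem}}.
#' @param params a \code{FusionParams} (solver caps).
#' @return list with \code{selected} (per-tree node index vectors),
#'   \code{links} (data.frame \code{tree}, \code{from}, \code{to},
#'   \code{theta}), \code{objective}, and \code{exact}.
#' @export
solveFusionBlock <- function(problem, params = fusionParams()) {
  nt <- length(problem$parents)
  thr <- problem$linkThreshold
  netw <- lapply(problem$links, function(m) {
    m <- m - thr
    m[m <= 0] <- 0
    m
  })
  counts <- vapply(problem$parents, count_antichains, 0)
  sizes <- vapply(problem$parents, max_antichain_size, 0L)
  work <- 0
  if (all(counts <= params@maxAntichains) && all(sizes <= 20L)) {
    for (i in seq_len(nt - 1L))
      work <- work + counts[i] * counts[i + 1L] *
        sizes[i] * 2^min(sizes[i], sizes[i + 1L])
  } else {
    work <- Inf
  }
  if (is.finite(work) && work <= params@maxExactWork) {
    solve_fusion_exact(problem, netw, params)
  } else {
    warning("fusion block too large for the exact solver; ",
            "using greedy matching (solution may be suboptimal)")
    solve_fusion_greedy(problem, netw)
  }
}

solve_fusion_exact <- function(problem, netw, params) {
  nt <- length(problem$parents)
  ac <- lapply(problem$parents, enumerate_antichains,
               cap = params@maxAntichains)
  qsum <- lapply(seq_len(nt), function(i)
    vapply(ac[[i]], function(s) sum(problem$qualities[[i]][s]), 0))
  # forward DP over antichain choices
  val <- qsum[[1]]
  back <- vector("list", nt)
  for (i in seq_len(nt - 1L)) {
    M <- cpp_matching_values(netw[[i]], ac[[i]], ac[[i + 1L]])
    tot <- M + val  # recycles val down columns: tot[a, b] = val[a] + M[a, b]
    best_a <- max.col(t(tot), ties.method = "first")
    val <- tot[cbind(best_a, seq_along(ac[[i + 1L]]))] + qsum[[i + 1L]]
    back[[i + 1L]] <- best_a
  }
  sel_idx <- integer(nt)
  sel_idx[nt] <- which.max(val)
  objective <- max(val)
  for (i in rev(seq_len(nt - 1L)))
    sel_idx[i] <- back[[i + 1L]][sel_idx[i + 1L]]
  selected <- lapply(seq_len(nt), function(i) ac[[i]][[sel_idx[i]]])
  links <- collect_links(selected, netw, problem, exact = TRUE)
  list(selected = selected, links = links, objective = objective,
       exact = TRUE)
}

collect_links <- function(selected, netw, problem, exact) {
  out <- list()
  for (i in seq_along(netw)) {
    s1 <- selected[[i]]
    s2 <- selected[[i + 1L]]
    if (!length(s1) || !length(s2)) next
    sub <- netw[[i]][s1, s2, drop = FALSE]
    if (all(sub <= 0)) next
    m <- cpp_max_matching(sub)
    if (nrow(m$pairs))
      out[[length(out) + 1L]] <- data.frame(
        tree = i, from = s1[m$pairs[, 1]], to = s2[m$pairs[, 2]],
        theta = problem$links[[i]][cbind(s1[m$pairs[, 1]],
                                         s2[m$pairs[, 2]])])
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(tree = integer(), from = integer(), to = integer(),
                  theta = numeric())
}

# greedy fallback: per-tree max-quality antichain, then links in descending
# similarity, each accepted only if its end nodes are selected and their
# in/out slots are free
solve_fusion_greedy <- function(problem, netw) {
  nt <- length(problem$parents)
  selected <- lapply(seq_len(nt), function(i)
    best_quality_antichain(problem$parents[[i]], problem$qualities[[i]]))
  links <- list()
  objective <- sum(vapply(seq_len(nt), function(i)
    sum(problem$qualities[[i]][selected[[i]]]), 0))
  for (i in seq_len(nt - 1L)) {
    s1 <- selected[[i]]
    s2 <- selected[[i + 1L]]
    if (!length(s1) || !length(s2)) next
    sub <- netw[[i]][s1, s2, drop = FALSE]
    cand <- which(sub > 0, arr.ind = TRUE)
    if (!nrow(cand)) next
    cand <- cand[order(-sub[cand], cand[, 1], cand[, 2]), , drop = FALSE]
    out_used <- logical(length(s1))
    in_used <- logical(length(s2))
    for (r in seq_len(nrow(cand))) {
      a <- cand[r, 1]
      b <- cand[r, 2]
      if (out_used[a] || in_used[b]) next
      out_used[a] <- TRUE
      in_used[b] <- TRUE
      links[[length(links) + 1L]] <- data.frame(
        tree = i, from = s1[a], to = s2[b],
        theta = problem$links[[i]][s1[a], s2[b]])
      objective <- objective + sub[a, b]
    }
  }
  links <- if (length(links)) do.call(rbind, links)
    else data.frame(tree = integer(), from = integer(), to = integer(),
                    theta = numeric())
  list(selected = selected, links = links, objective = objective,
       exact = FALSE)
}

best_quality_antichain <- function(parent, quality) {
  kids <- children_of(parent)
  root <- which(parent == 0L)
  rec <- function(v) {
    if (!length(kids[[v]])) return(list(val = quality[v], set = v))
    below <- lapply(kids[[v]], rec)
    bv <- sum(vapply(below, `[[`, 0, "val"))
    if (quality[v] >= bv) list(val = quality[v], set = v)
    else list(val = bv,
              set = unlist(lapply(below, `[[`, "set"), use.names = FALSE))
  }
  as.integer(rec(root[1])$set)
}

#' Tracking timescale of the drift correction
#'
#' The duration over which spike waveforms are assumed stable: a 1000-spike
#' local-clustering block lasts \code{1000 / eventRate} seconds and a
#' 1000-centroid fusion block spans \code{1000 / centroidsPer1000} such
#' blocks, so the timescale is \code{(1000 / eventRate) * 1000 /
#' centroidsPer1000} seconds.
#'
#' @param eventRate mean spike detection rate, Hz.
#' @param centroidsPer1000 centroids produced per 1000-spike block.
#' @return timescale in seconds.
#' @export
trackingTimescale <- function(eventRate, centroidsPer1000) {
  if (eventRate <= 0 || centroidsPer1000 <= 0)
    stop("eventRate and centroidsPer1000 must be positive")
  (1000 / eventRate) * 1000 / centroidsPer1000
}
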