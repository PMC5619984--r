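cross_dist <- function(a, b) {
  # Euclidean distances between rows of a and rows of b
  a2 <- rowSums(a^2)
  b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

# Convert an SpcTree over a block of centroids into fusion nodes. Chains of
# nodes with identical membership (a cluster stable across temperatures)
# collapse to their deepest copy: that copy has the highest quality and the
# same links and exclusions, so dropping the shallower copies preserves the
# optimum while shrinking the search space. Node mean waveforms are
# spike-count-weighted means of their member centroids (i.e. the average
# spike waveform of the underlying spikes).
tree_fusion_nodes <- function(tree, wf_block, counts_block, centroid_ids) {
  nn <- length(tree@members)
  keep <- vapply(seq_len(nn), function(i) {
    kids <- tree@children[[i]]
    !(length(kids) == 1L &&
        length(tree@members[[kids]]) == length(tree@members[[i]]))
  }, TRUE)
  idx <- which(keep)
  # nearest kept descendant replaces a dropped node as parent anchor
  remap <- integer(nn)
  for (i in rev(seq_len(nn)))
    remap[i] <- if (keep[i]) i else remap[tree@children[[i]][1]]
  new_id <- integer(nn)
  new_id[idx] <- seq_along(idx)
  parent <- integer(length(idx))
  for (j in seq_along(idx)) {
    p <- tree@parent[idx[j]]
    while (p > 0L && !keep[p]) p <- tree@parent[p]
    parent[j] <- if (p > 0L) new_id[p] else 0L
  }
  # guard: the root of the reduced tree is the deepest copy of the original
  # root chain, found through remap
  root <- new_id[remap[which(tree@depth == 0L)]]
  parent[root] <- 0L
  quality <- vapply(idx, function(i) nodeQuality(tree, i), 0)
  members <- lapply(idx, function(i) centroid_ids[tree@members[[i]]])
  wts <- lapply(idx, function(i) {
    m <- tree@members[[i]]
    w <- counts_block[m]
    colSums(wf_block[m, , drop = FALSE] * w) / sum(w)
  })
  leaves <- which(vapply(seq_along(idx), function(j)
    !any(parent == j), TRUE))
  list(parent = parent, quality = quality, members = members,
       waveforms = do.call(rbind, wts), leaves = leaves)
}

#' Fuse a centroid sequence into single-unit chains (Step 2)
#'
#' Pools de-noised centroids into blocks of \code{centroidsPerBlock}
#' consecutive centroids, builds an SPC cluster tree per block, and links
#' tree nodes through time by solving overlapping segmentation-fusion binary
#' programs (\code{treesPerIlp} trees per program, \code{ilpOverlap} trees of
#' overlap). A link chosen by every program covering its tree pair is
#' retained; retained links are chained into time-extended sequences of nodes,
#' each a putative single unit. Centroids in no chain are attached to the
#' most similar chain when their similarity exceeds
#' \code{stragglerThreshold}. Optionally, temporally overlapping chains whose
#' translation-invariant waveform distance is low (alignment-flip duplicates
#' of one unit) are merged.
#'
#' Link similarities are the sigmoid-mapped Euclidean distances between node
#' mean waveforms; raw uV distances are multiplied by \code{distScale}. The
#' default calibration maps the median nearest-neighbour distance between
#' leaf-node mean waveforms of adjacent trees to \code{sigmoidK} (the
#' half-similarity distance), so typical same-unit drift steps are linkable
#' while nearest cross-unit centroids -- a few times the typical step -- fall
#' below the link threshold.
#'
#' @param centroids a \code{\linkS4class{CentroidSet}}.
#' @param params a \code{FusionParams}.
#' @param seed integer seed for the SPC sweeps.
#' @param method clustering engine for the centroid trees.
#' @param mergeChains run \code{\link{mergeTranslationInvariant}} afterwards.
#' @param extents optional [centroids x 2] matrix of first/last member spike
#'   times, used as chain time spans during merging (defaults to the
#'   centroid median times).
#' @param verbose print progress.
#' @return A \code{\linkS4class{ChainSet}} whose \code{log} records the
#'   distance scale, per-window objectives and solver exactness.
#' @export
fuseCentroids <- function(centroids, params = fusionParams(), seed = NULL,
                          method = "spc", mergeChains = TRUE, extents = NULL,
                          verbose = FALSE) {
  M <- nCentroids(centroids)
  if (M < 2L)
    return(new("ChainSet", chains = list(), unassigned = seq_len(M),
               nCentroids = M, log = list(distScale = NA_real_)))
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  wf <- waveforms(centroids)
  starts <- seq(1L, M, by = params@centroidsPerBlock)
  trees <- vector("list", length(starts))
  nodes <- vector("list", length(starts))
  for (b in seq_along(starts)) {
    b0 <- starts[b]
    b1 <- min(b0 + params@centroidsPerBlock - 1L, M)
    ids <- b0:b1
    labels <- suppressWarnings(
      runSpcSweep(wf[ids, , drop = FALSE], tMin = 0, tMax = params@tMax,
                  tStep = params@tStep, method = method))
    trees[[b]] <- buildClusterTree(labels)
    nodes[[b]] <- tree_fusion_nodes(trees[[b]], wf[ids, , drop = FALSE],
                                    centroids@counts[ids], ids)
    if (verbose) message(sprintf("tree %d/%d: %d node(s)", b, length(starts),
                                 length(nodes[[b]]$quality)))
  }
  nt <- length(nodes)
  scale <- params@distScale
  if (!is.finite(scale))
    scale <- calibrate_dist_scale(nodes, params)
  theta <- vector("list", max(nt - 1L, 0L))
  for (i in seq_len(nt - 1L)) {
    d <- cross_dist(nodes[[i]]$waveforms, nodes[[i + 1L]]$waveforms)
    th <- linkWeight(d * scale, params@sigmoidS, params@sigmoidK)
    th[th >= 1] <- 1 - 1e-12
    th[th <= 0] <- 1e-12
    theta[[i]] <- th
  }
  # overlapping solver windows covering every tree pair
  if (nt <= params@treesPerIlp) {
    wins <- list(seq_len(nt))
  } else {
    stride <- params@treesPerIlp - params@ilpOverlap
    s <- unique(c(seq(1L, nt - params@treesPerIlp, by = stride),
                  nt - params@treesPerIlp + 1L))
    wins <- lapply(s, function(x) x:(x + params@treesPerIlp - 1L))
  }
  chosen <- vector("list", length(wins))
  sols <- vector("list", length(wins))
  exact <- logical(length(wins))
  objectives <- numeric(length(wins))
  for (w in seq_along(wins)) {
    tr <- wins[[w]]
    prob <- fusionProblem(
      parents = lapply(nodes[tr], `[[`, "parent"),
      qualities = lapply(nodes[tr], `[[`, "quality"),
      links = theta[tr[-length(tr)]],
      linkThreshold = params@linkThreshold)
    sol <- solveFusionBlock(prob, params)
    lk <- sol$links
    if (nrow(lk)) lk$tree <- tr[lk$tree]  # to global tree indices
    chosen[[w]] <- lk
    sols[[w]] <- sol
    exact[w] <- sol$exact
    objectives[w] <- sol$objective
  }
  # a link is retained only if every window covering its tree pair chose it
  retained <- list()
  for (i in seq_len(nt - 1L)) {
    cover <- which(vapply(wins, function(tr)
      i %in% tr && (i + 1L) %in% tr, TRUE))
    sets <- lapply(chosen[cover], function(lk)
      lk[lk$tree == i, c("from", "to", "theta"), drop = FALSE])
    keys <- lapply(sets, function(s) paste(s$from, s$to))
    common <- Reduce(intersect, keys)
    if (length(common)) {
      s1 <- sets[[1]]
      keep <- s1[paste(s1$from, s1$to) %in% common, , drop = FALSE]
      keep$tree <- i
      retained[[length(retained) + 1L]] <- keep
    }
  }
  retained <- if (length(retained)) do.call(rbind, retained)
    else data.frame(tree = integer(), from = integer(), to = integer(),
                    theta = numeric())
  chains <- chain_links(retained, nodes)
  # selected nodes without any retained link become single-node chains: slow
  # units may contribute fewer than one centroid per tree, so their nodes
  # cannot link; the translation-invariant merge and the cross-gap proposal
  # stage reunite these fragments downstream
  used <- unlist(chains, use.names = FALSE)
  for (w in seq_along(wins)) {
    tr <- wins[[w]]
    for (i in seq_along(tr)) {
      for (v in sols[[w]]$selected[[i]]) {
        mem <- nodes[[tr[i]]]$members[[v]]
        if (length(intersect(mem, used))) next
        chains[[length(chains) + 1L]] <- sort(mem)
        used <- c(used, mem)
      }
    }
  }
  unassigned <- setdiff(seq_len(M), unlist(chains, use.names = FALSE))
  res <- attach_stragglers(chains, unassigned, wf, scale, params)
  cs <- new("ChainSet", chains = res$chains,
            unassigned = as.integer(sort(res$unassigned)), nCentroids = M,
            log = list(distScale = scale, exact = exact,
                       objectives = objectives, nTrees = nt))
  if (mergeChains)
    cs <- mergeTranslationInvariant(cs, centroids, params, extents = extents)
  cs
}

calibrate_dist_scale <- function(nodes, params) {
  nn <- numeric()
  for (i in seq_len(length(nodes) - 1L)) {
    a <- nodes[[i]]$waveforms[nodes[[i]]$leaves, , drop = FALSE]
    b <- nodes[[i + 1L]]$waveforms[nodes[[i + 1L]]$leaves, , drop = FALSE]
    d <- cross_dist(a, b)
    nn <- c(nn, apply(d, 1, min))
  }
  if (!length(nn)) {  # single tree: use within-tree leaf spacing
    a <- nodes[[1]]$waveforms[nodes[[1]]$leaves, , drop = FALSE]
    if (nrow(a) < 2) return(1)
    d <- cross_dist(a, a)
    diag(d) <- Inf
    nn <- apply(d, 1, min)
  }
  m <- stats::median(nn[is.finite(nn)])
  if (!is.finite(m) || m <= 0) return(1)
  # the typical adjacent-tree nearest-neighbour step maps to k, the sigmoid's
  # half-similarity distance; nearest cross-unit centroids (a few times the
  # typical step) then fall below the link threshold
  params@sigmoidK / m
}

# follow retained links into chains of nodes, then expand to centroid ids
chain_links <- function(links, nodes) {
  if (!nrow(links)) return(list())
  key <- function(t, n) paste(t, n, sep = ":")
  # defensive de-duplication: keep the strongest link per out/in slot
  links <- links[order(-links$theta), , drop = FALSE]
  links <- links[!duplicated(key(links$tree, links$from)) &
                 !duplicated(key(links$tree + 1L, links$to)), , drop = FALSE]
  nxt <- stats::setNames(key(links$tree + 1L, links$to),
                         key(links$tree, links$from))
  has_in <- key(links$tree + 1L, links$to)
  heads <- setdiff(key(links$tree, links$from), has_in)
  chains <- list()
  for (h in heads) {
    path <- cur <- h
    repeat {
      nx <- nxt[cur]
      if (is.na(nx)) break
      cur <- unname(nx)
      path <- c(path, cur)
    }
    parts <- strsplit(path, ":", fixed = TRUE)
    cents <- unlist(lapply(parts, function(p)
      nodes[[as.integer(p[1])]]$members[[as.integer(p[2])]]),
      use.names = FALSE)
    chains[[length(chains) + 1L]] <- sort(unique(cents))
  }
  chains
}

attach_stragglers <- function(chains, unassigned, wf, scale, params) {
  if (!length(chains) || !length(unassigned))
    return(list(chains = chains, unassigned = unassigned))
  chained <- unlist(chains, use.names = FALSE)
  chain_of <- rep(seq_along(chains), lengths(chains))
  d <- cross_dist(wf[unassigned, , drop = FALSE],
                  wf[chained, , drop = FALSE])
  th <- linkWeight(d * scale, params@sigmoidS, params@sigmoidK)
  best <- max.col(th, ties.method = "first")
  bestv <- th[cbind(seq_along(unassigned), best)]
  take <- bestv > params@stragglerThreshold
  for (i in which(take)) {
    ci <- chain_of[best[i]]
    chains[[ci]] <- sort(c(chains[[ci]], unassigned[i]))
  }
  list(chains = chains, unassigned = unassigned[!take])
}

# translation-invariant distances between all row pairs of M, vectorised over
# shifts (one BLAS cross-distance per shift, elementwise minimum)
ti_cross_dist <- function(M, n_ch, sps, shift_range) {
  D <- NULL
  for (s in -shift_range:shift_range) {
    colsA <- colsB <- integer()
    for (ch in seq_len(n_ch)) {
      base <- (ch - 1L) * sps
      if (s >= 0) {
        a <- (1 + s):sps
        b <- 1:(sps - s)
      } else {
        a <- 1:(sps + s)
        b <- (1 - s):sps
      }
      colsA <- c(colsA, base + a)
      colsB <- c(colsB, base + b)
    }
    d <- cross_dist(M[, colsA, drop = FALSE], M[, colsB, drop = FALSE]) *
      sqrt(sps / (sps - abs(s)))
    D <- if (is.null(D)) d else pmin(D, d)
  }
  D
}

ti_distance <- function(w1, w2, n_ch, sps, shift_range) {
  best <- Inf
  m1 <- matrix(w1, n_ch, sps, byrow = TRUE)
  m2 <- matrix(w2, n_ch, sps, byrow = TRUE)
  for (s in -shift_range:shift_range) {
    if (s >= 0) {
      a <- m1[, (1 + s):sps, drop = FALSE]
      b <- m2[, 1:(sps - s), drop = FALSE]
    } else {
      a <- m1[, 1:(sps + s), drop = FALSE]
      b <- m2[, (1 - s):sps, drop = FALSE]
    }
    d2 <- sum((a - b)^2) * sps / (sps - abs(s))
    if (d2 < best) best <- d2
  }
  sqrt(best)
}

#' Merge alignment-duplicate chains (translation-invariant distance)
#'
#' Waveforms with multiple near-equal extrema can be aligned to different
#' features, splitting one unit into several chains with mutually shifted
#' waveforms. Chains overlapping in time whose translation-invariant distance
#' (minimum Euclidean distance over integer shifts of up to
#' \code{shiftRange} samples, computed between count-weighted mean waveforms
#' in the overlap region) is low are merged, smallest distance first,
#' recursively until no overlapping pair remains below the cutoff (the
#' normalised distance at which the link sigmoid reaches 0.5).
#'
#' @param chainSet a \code{\linkS4class{ChainSet}}.
#' @param centroids the \code{CentroidSet} the chains index.
#' @param params a \code{FusionParams}.
#' @param distScale distance normalisation; defaults to the scale recorded in
#'   \code{chainSet@log}.
#' @param extents optional [centroids x 2] matrix of first/last member spike
#'   times; chains overlap when their spike extents do (median times alone
#'   make single-centroid chains point-like and never overlapping).
#' @return The merged \code{ChainSet}.
#' @export
mergeTranslationInvariant <- function(chainSet, centroids,
                                      params = fusionParams(),
                                      distScale = NULL, extents = NULL) {
  if (is.null(distScale)) distScale <- chainSet@log$distScale
  if (is.null(distScale) || !is.finite(distScale)) distScale <- 1
  cutoff <- params@sigmoidK / distScale
  ch <- chainSet@chains
  if (length(ch) < 2L) return(chainSet)
  wf <- waveforms(centroids)
  cnt <- centroids@counts
  tms <- centroids@medianTimes
  if (is.null(extents)) extents <- cbind(tms, tms)
  summary_of <- function(idx, window = NULL) {
    use <- idx
    if (!is.null(window)) {
      inw <- idx[tms[idx] >= window[1] & tms[idx] <= window[2]]
      if (length(inw)) use <- inw
    }
    w <- cnt[use]
    colSums(wf[use, , drop = FALSE] * w) / sum(w)
  }
  span_of <- function(idx) c(min(extents[idx, 1]), max(extents[idx, 2]))
  pair_dist <- function(ch, i, j) {
    sp <- rbind(span_of(ch[[i]]), span_of(ch[[j]]))
    ov <- c(max(sp[, 1]), min(sp[, 2]))
    if (ov[1] > ov[2]) return(Inf)
    ti_distance(summary_of(ch[[i]], ov), summary_of(ch[[j]], ov),
                centroids@nChannels, centroids@samplesPerSpike,
                params@shiftRange)
  }
  # whole-chain mean waveforms give a cheap vectorised lower screen; the
  # exact (overlap-region) distance is evaluated only for surviving pairs
  n <- length(ch)
  M <- do.call(rbind, lapply(ch, summary_of))
  spans_m <- t(vapply(ch, span_of, numeric(2)))
  D <- ti_cross_dist(M, centroids@nChannels, centroids@samplesPerSpike,
                     params@shiftRange)
  overlaps <- function(i, j)
    max(spans_m[i, 1], spans_m[j, 1]) <= min(spans_m[i, 2], spans_m[j, 2])
  alive <- rep(TRUE, n)
  exact <- matrix(Inf, n, n)
  need <- which(upper.tri(D) & D <= 3 * cutoff, arr.ind = TRUE)
  for (r in seq_len(nrow(need))) {
    i <- need[r, 1]
    j <- need[r, 2]
    if (overlaps(i, j)) exact[i, j] <- pair_dist(ch, i, j)
  }
  repeat {
    if (sum(alive) < 2L) break
    best <- which(exact == min(exact), arr.ind = TRUE)
    if (!is.finite(exact[best[1, 1], best[1, 2]]) ||
        exact[best[1, 1], best[1, 2]] > cutoff) break
    i <- best[1, 1]
    j <- best[1, 2]
    ch[[i]] <- sort(c(ch[[i]], ch[[j]]))
    alive[j] <- FALSE
    exact[j, ] <- Inf
    exact[, j] <- Inf
    # refresh the merged chain's screen and exact distances
    M[i, ] <- summary_of(ch[[i]])
    spans_m[i, ] <- span_of(ch[[i]])
    di <- ti_cross_dist(rbind(M[i, ], M[alive, , drop = FALSE]),
                        centroids@nChannels, centroids@samplesPerSpike,
                        params@shiftRange)[1, -1]
    others <- which(alive)
    exact[i, ] <- Inf
    exact[, i] <- Inf
    for (k in seq_along(others)) {
      o <- others[k]
      if (o == i || di[k] > 3 * cutoff || !overlaps(i, o)) next
      exact[min(i, o), max(i, o)] <- pair_dist(ch, i, o)
    }
  }
  ch <- ch[alive]
  new("ChainSet", chains = ch, unassigned = chainSet@unassigned,
      nCentroids = chainSet@nCentroids,
      log = c(chainSet@log, list(mergedTo = length(ch))))
}

#' Per-chain spike times
#'
#' Expands each chain through its centroids' member snippet indices to the
#' spike times of the putative unit.
#'
#' @param chainSet a \code{ChainSet}.
#' @param centroids the \code{CentroidSet} the chains index.
#' @param snippets the source \code{SnippetSet} (or a numeric vector of peak
#'   times in samples).
#' @param unit \code{"s"} for seconds (default) or \code{"samples"}.
#' @return list of sorted numeric vectors, one per chain.
#' @export
chainSpikeTimes <- function(chainSet, centroids, snippets, unit = "s") {
  times <- if (is(snippets, "SnippetSet")) peakTimes(snippets) else snippets
  fs <- if (is(snippets, "SnippetSet")) snippets@sampleRate else 1
  lapply(chainSet@chains, function(ci) {
    idx <- unlist(centroids@members[ci], use.names = FALSE)
    t <- sort(times[idx])
    if (unit == "s") t / fs else t
  })
}
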