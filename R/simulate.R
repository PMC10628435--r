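# Synthetic splice-graph instances with known ground truth, fixed hand-built
# gadgets, subpath-constraint generation, and the brute-force enumeration
# oracles that ground the safety tests.

# run expr with a local RNG seed, restoring the caller's RNG state
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

.superposeTranscripts <- function(transcripts, abundances) {
  from <- integer(); to <- integer(); flow <- numeric()
  for (i in seq_along(transcripts)) {
    p <- transcripts[[i]]
    for (j in seq_len(length(p) - 1L)) {
      e <- which(from == p[j] & to == p[j + 1L])
      if (length(e)) {
        flow[e] <- flow[e] + abundances[i]
      } else {
        from <- c(from, p[j]); to <- c(to, p[j + 1L])
        flow <- c(flow, abundances[i])
      }
    }
  }
  ord <- order(from, to)
  flowNetwork(from[ord], to[ord], flow[ord])
}

#' Generate a random splice-graph instance with known ground truth
#'
#' Emulates the construction of benchmark flow graphs: a random DAG skeleton
#' is drawn on a topological order with unique source (node 0) and sink
#' (node n-1), `t` random source-to-sink transcript paths are sampled over it
#' with integer abundances, and the edge flows are their perfect
#' superposition, so flow conservation holds by construction and the
#' transcripts form a ground-truth flow decomposition. Funnels (instances with
#' a unique decomposition) are rejected and resampled when
#' `requireNontrivial` is set, mirroring how trivial instances are filtered
#' from the benchmark collections.
#'
#' Transcripts duplicated as node sequences have their abundances merged, so
#' the returned instance may have fewer than `t` distinct transcripts.
#'
#' @param nNodes Number of skeleton nodes (>= 3).
#' @param nTranscripts Number of transcript paths to sample (>= 1).
#' @param weightSampler Function `n -> n` positive integer abundances; the
#'   default samples uniformly from 1..100. A heavy-tailed alternative such as
#'   `function(n) 1L + stats::rpois(n, 2)^2L` can be supplied for realism.
#' @param seed Integer seed; instances are reproducible for a fixed seed and
#'   the caller's RNG state is left untouched.
#' @param requireNontrivial Reject funnel instances and resample.
#' @param maxTries Bound on resampling attempts.
#' @return A [GroundTruthInstance].
#' @examples
#' inst <- generateInstance(6, 2, seed = 1)
#' flowViolations(instanceNetwork(inst))
#' @export
generateInstance <- function(nNodes, nTranscripts,
                             weightSampler = function(n) {
                               sample.int(100L, n, replace = TRUE)
                             },
                             seed = 1L, requireNontrivial = TRUE,
                             maxTries = 200L) {
  stopifnot(nNodes >= 3, nTranscripts >= 1)
  .withSeed(seed, {
    for (try in seq_len(maxTries)) {
      n <- nNodes
      # skeleton: every node reaches the sink and is reached from the source
      pairs <- matrix(integer(0), ncol = 2)
      for (v in seq_len(n - 1L)) {
        u <- if (v == 1L) 0L else sample(0:(v - 1L), 1L)
        pairs <- rbind(pairs, c(u, v))
      }
      for (v in 0:(n - 2L)) {
        w <- if (v == n - 2L) n - 1L else sample((v + 1L):(n - 1L), 1L)
        pairs <- rbind(pairs, c(v, w))
      }
      extra <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE) - 1L
      keep <- stats::runif(nrow(extra)) < 2 / n
      pairs <- unique(rbind(pairs, extra[keep, , drop = FALSE]))
      adj <- split(pairs[, 2], pairs[, 1])

      walk <- function() {
        v <- 0L
        path <- v
        while (v != n - 1L) {
          outs <- adj[[as.character(v)]]
          v <- if (length(outs) == 1L) outs else sample(outs, 1L)
          path <- c(path, v)
        }
        path
      }
      transcripts <- list()
      for (i in seq_len(nTranscripts)) {
        p <- walk()
        for (retry in 1:20) {
          if (!any(vapply(transcripts, identical, logical(1), y = p))) break
          p <- walk()
        }
        transcripts <- c(transcripts, list(p))
      }
      abundances <- as.integer(weightSampler(length(transcripts)))
      stopifnot(all(abundances >= 1))
      # merge duplicates
      keys <- vapply(transcripts, .pathKey, character(1))
      if (anyDuplicated(keys)) {
        abundances <- as.integer(tapply(abundances, keys, sum)[unique(keys)])
        transcripts <- transcripts[!duplicated(keys)]
      }
      net <- .superposeTranscripts(transcripts, abundances)
      net@graphId <- sprintf("sim_seed%d_try%d", seed, try)
      if (requireNontrivial && isFunnel(net)) next
      return(new("GroundTruthInstance", network = net,
                 transcripts = transcripts, abundances = abundances,
                 constraints = list(), seed = as.integer(seed),
                 params = list(nNodes = nNodes, nTranscripts = nTranscripts,
                               requireNontrivial = requireNontrivial,
                               tries = try)))
    }
    stop(sprintf(
      "could not generate a non-funnel instance in %d tries (nNodes=%d, t=%d, seed=%d)",
      maxTries, nNodes, nTranscripts, seed))
  })
}

#' Fixed hand-built gadget instances
#'
#' Small instances with fully understood solution structure, used as fixtures:
#' \describe{
#'   \item{`path`}{s -> a -> t with flow 5: a funnel with one transcript.}
#'   \item{`crossing`}{Two transcripts crossing at a hub node; both edges of
#'     every pair carry flow 2, so two distinct minimum decompositions exist
#'     and only the four arms are safe.}
#'   \item{`g4`}{A graph with a unique minimum decomposition of size 2 but
#'     many larger decompositions; the minimum-decomposition safe paths are
#'     the two full transcripts while safe-for-all-FDs paths are shorter.}
#'   \item{`three_path`}{Smallest instance whose minimum decomposition needs
#'     three paths although the source degree is two.}
#' }
#'
#' @param name One of `"path"`, `"crossing"`, `"g4"`, `"three_path"`.
#' @return A [GroundTruthInstance].
#' @examples
#' gadget("crossing")
#' @export
gadget <- function(name = c("path", "crossing", "g4", "three_path")) {
  name <- match.arg(name)
  spec <- switch(name,
    path = list(
      transcripts = list(c(0L, 1L, 2L)),
      abundances = 5L),
    crossing = list(
      # s=0 a=1 b=2 c=3 d=4 e=5 t=6
      transcripts = list(c(0L, 1L, 3L, 4L, 6L), c(0L, 2L, 3L, 5L, 6L)),
      abundances = c(2L, 2L)),
    g4 = list(
      # s=0 a=1 b=2 c=3 d=4 t=5
      transcripts = list(c(0L, 1L, 2L, 4L, 5L), c(0L, 2L, 3L, 5L)),
      abundances = c(1L, 2L)),
    three_path = list(
      # s=0 a=1 b=2 t=3
      transcripts = list(c(0L, 1L, 3L), c(0L, 1L, 2L, 3L), c(0L, 2L, 3L)),
      abundances = c(1L, 1L, 1L))
  )
  net <- .superposeTranscripts(spec$transcripts, spec$abundances)
  net@graphId <- name
  new("GroundTruthInstance", network = net, transcripts = spec$transcripts,
      abundances = spec$abundances, constraints = list(),
      seed = NA_integer_, params = list(gadget = name))
}

#' Generate subpath constraints from ground-truth transcripts
#'
#' Emulates long-read-derived constraints: floor(t/2) transcripts are chosen
#' (seeded, without replacement) and each contributes the shortest prefix of
#' its path that contains three nontrivial junctions; transcripts with fewer
#' than three junctions contribute their full path. A junction is an internal
#' node of the graph with in-degree >= 2 or out-degree >= 2
#' (`junctionRule = "any"`, the default) or with out-degree >= 2 only
#' (`"out"`).
#'
#' @param instance A [GroundTruthInstance].
#' @param seed Integer seed for the transcript choice.
#' @param junctionRule `"any"` or `"out"`.
#' @return A list of integer node sequences (possibly empty); each constraint
#'   has at least one edge and is satisfied by the ground truth, so the
#'   constrained decomposition model is always feasible.
#' @export
makeSubpathConstraints <- function(instance, seed = 1L,
                                   junctionRule = c("any", "out")) {
  junctionRule <- match.arg(junctionRule)
  net <- instance@network
  t <- length(instance@transcripts)
  nSel <- t %/% 2L
  if (nSel == 0L) return(list())
  sel <- .withSeed(seed, sample.int(t, nSel))
  internal <- setdiff(net@nodes, c(net@source, net@sink))
  isJunction <- vapply(internal, function(v) {
    outd <- length(.outEdges(net, v))
    ind <- length(.inEdges(net, v))
    if (junctionRule == "any") outd >= 2L || ind >= 2L else outd >= 2L
  }, logical(1))
  junctions <- internal[isJunction]
  lapply(instance@transcripts[sel], function(p) {
    pos <- which(p %in% junctions)
    if (length(pos) < 3L) p else p[seq_len(pos[3L])]
  })
}

# all source-to-sink paths as edge-index vectors, deterministic order
.allStPaths <- function(network) {
  out <- list()
  recurse <- function(v, edges) {
    if (v == network@sink) {
      out[[length(out) + 1L]] <<- edges
      return(invisible())
    }
    for (e in sort(.outEdges(network, v))) {
      recurse(network@to[e], c(edges, e))
    }
  }
  recurse(network@source, integer(0))
  out
}

.oracleGuard <- function(network, maxFlow, maxEdges) {
  f <- sum(network@flow[.outEdges(network, network@source)])
  if (f > maxFlow || length(network@from) > maxEdges) {
    stop(sprintf(
      "instance too large for the enumeration oracle (source outflow %g > %g or %d edges > %d)",
      f, maxFlow, length(network@from), maxEdges))
  }
}

#' Brute-force enumeration of flow decompositions
#'
#' Test oracle: exhaustively enumerates every multiset of exactly `k` weighted
#' source-to-sink paths whose superposition equals the flow (each multiset
#' reported once, in canonical order). Guarded to oracle-scale instances;
#' intended to ground the solver-based code paths, never to replace them.
#'
#' @param network A valid [FlowNetwork].
#' @param k Decomposition size; `NULL` enumerates decompositions of every size
#'   (finite, since weights are >= 1).
#' @param maxFlow,maxEdges Guards on total source out-flow and edge count.
#' @return List of [WeightedDecomposition] objects.
#' @examples
#' length(enumerateAllFDs(instanceNetwork(gadget("crossing")), 2)) # 2
#' @export
enumerateAllFDs <- function(network, k = NULL, maxFlow = 10, maxEdges = 14) {
  .stopifInvalid(network)
  .oracleGuard(network, maxFlow, maxEdges)
  paths <- .allStPaths(network)
  m <- length(network@from)
  sOut <- .outEdges(network, network@source)
  found <- list()
  recurse <- function(residual, chosenIdx, chosenW, lastIdx, lastW) {
    if (all(residual == 0)) {
      if (is.null(k) || length(chosenIdx) == k) {
        found[[length(found) + 1L]] <<- list(idx = chosenIdx, w = chosenW)
      }
      return(invisible())
    }
    if (!is.null(k) && length(chosenIdx) >= k) return(invisible())
    # each positive-residual source edge needs its own remaining path
    need <- sum(residual[sOut] > 0)
    if (!is.null(k) && need > k - length(chosenIdx)) return(invisible())
    for (idx in lastIdx:length(paths)) {
      e <- paths[[idx]]
      maxw <- min(residual[e])
      if (maxw < 1) next
      wFrom <- if (idx == lastIdx) lastW else 1L
      if (wFrom > maxw) next
      for (w in wFrom:maxw) {
        r2 <- residual
        r2[e] <- r2[e] - w
        recurse(r2, c(chosenIdx, idx), c(chosenW, w), idx, w)
      }
    }
  }
  recurse(network@flow, integer(0), integer(0), 1L, 1L)
  lapply(found, function(d) {
    new("WeightedDecomposition",
        paths = lapply(paths[d$idx], function(e) .nodesFromEdges(network, e)),
        edgePaths = paths[d$idx],
        weights = as.integer(d$w))
  })
}

#' Brute-force maximal safe paths
#'
#' Test oracle for the safety algorithms: enumerates all minimum
#' decompositions (`mode = "mfd"`) or all decompositions of every size
#' (`mode = "all_fd"`); a candidate window is safe iff it is a contiguous
#' subpath of some member of every decomposition; maximal safe windows are
#' returned canonicalized.
#'
#' @inheritParams enumerateAllFDs
#' @param mode `"mfd"` or `"all_fd"`.
#' @return List of integer node sequences.
#' @examples
#' bruteForceSafe(instanceNetwork(gadget("g4")), "all_fd")
#' @export
bruteForceSafe <- function(network, mode = c("mfd", "all_fd"),
                           maxFlow = 10, maxEdges = 14) {
  mode <- match.arg(mode)
  if (mode == "mfd") {
    decs <- list()
    k <- lowerBoundK(network)
    repeat {
      decs <- enumerateAllFDs(network, k, maxFlow, maxEdges)
      if (length(decs)) break
      k <- k + 1L
    }
  } else {
    decs <- enumerateAllFDs(network, NULL, maxFlow, maxEdges)
  }
  windows <- list()
  for (p in decs[[1]]@paths) {
    L <- length(p)
    for (a in seq_len(L - 1L)) {
      for (b in (a + 1L):L) {
        windows <- c(windows, list(p[a:b]))
      }
    }
  }
  windows <- windows[!duplicated(vapply(windows, .pathKey, character(1)))]
  isSafe <- vapply(windows, function(w) {
    all(vapply(decs, function(d) {
      any(vapply(d@paths, function(p) .isSubpath(w, p), logical(1)))
    }, logical(1)))
  }, logical(1))
  canonicalizePaths(windows[isSafe])
}
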