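#' Audit the flow-network invariants
#'
#' Checks the domain invariants of a [FlowNetwork] and returns a description
#' of every violation found (an empty character vector means the network is a
#' valid acyclic flow network): acyclicity, exactly one source and one sink,
#' strictly positive edge flows, and flow conservation at every node other
#' than the source and the sink.
#'
#' @param network A [FlowNetwork].
#' @return Character vector of violation descriptions; `character(0)` when all
#'   invariants hold.
#' @examples
#' bad <- flowNetwork(from = c(0L, 1L), to = c(1L, 2L), flow = c(5, 4))
#' flowViolations(bad)
#' @export
flowViolations <- function(network) {
  msg <- character()
  if (length(network@from) == 0L) {
    return("network has no edges")
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(network@from),
               to = as.character(network@to)),
    vertices = data.frame(name = as.character(network@nodes)))
  if (!igraph::is_dag(g)) {
    msg <- c(msg, "graph is not acyclic")
  }
  sources <- setdiff(network@nodes, network@to)
  sinks <- setdiff(network@nodes, network@from)
  if (length(sources) != 1L) {
    msg <- c(msg, sprintf("expected exactly one source, found %d (%s)",
                          length(sources), paste(sources, collapse = " ")))
  } else if (sources != network@source) {
    msg <- c(msg, sprintf("designated source %d has incoming edges",
                          network@source))
  }
  if (length(sinks) != 1L) {
    msg <- c(msg, sprintf("expected exactly one sink, found %d (%s)",
                          length(sinks), paste(sinks, collapse = " ")))
  } else if (sinks != network@sink) {
    msg <- c(msg, sprintf("designated sink %d has outgoing edges",
                          network@sink))
  }
  bad <- which(network@flow < 1 | network@flow != round(network@flow))
  for (e in bad) {
    msg <- c(msg, sprintf("edge %d -> %d has non positive-integer flow %g",
                          network@from[e], network@to[e], network@flow[e]))
  }
  internal <- setdiff(network@nodes, c(network@source, network@sink))
  for (v in internal) {
    fin <- sum(network@flow[.inEdges(network, v)])
    fout <- sum(network@flow[.outEdges(network, v)])
    if (fin != fout) {
      msg <- c(msg, sprintf(
        "flow conservation violated at node %d: in %g != out %g", v, fin,
        fout))
    }
  }
  msg
}

.stopifInvalid <- function(network) {
  v <- flowViolations(network)
  if (length(v)) {
    stop("invalid flow network: ", paste(v, collapse = "; "))
  }
  invisible(network)
}

#' Excess flow of a path
#'
#' The excess flow of a path P is the flow on its first edge minus the total
#' flow on edges leaving the internal nodes of P other than the edges of P
#' itself. A path with positive excess flow is contained in some path of
#' every flow decomposition (of any size), which gives a linear-time safety
#' test that avoids the integer program entirely.
#'
#' @param network A valid [FlowNetwork].
#' @param path Integer vector of node identifiers (at least one edge), or a
#'   `list(edges = ...)` of edge indices for paths of contracted multigraphs.
#' @return For `excessFlow`, a single number (a single-edge path returns its
#'   edge flow); for `isSafeAllFDs`, `TRUE` iff the excess flow is positive.
#' @examples
#' g4 <- instanceNetwork(gadget("g4"))
#' excessFlow(g4, c(0L, 1L, 2L, 4L)) # -1: not safe for all FDs
#' excessFlow(g4, c(0L, 1L, 2L))     # 1: safe for all FDs
#' @export
excessFlow <- function(network, path) {
  p <- .asPath(network, path)
  first <- p$edges[1L]
  internal <- p$nodes[-c(1L, length(p$nodes))]
  off <- 0
  for (v in internal) {
    out <- .outEdges(network, v)
    off <- off + sum(network@flow[setdiff(out, p$edges)])
  }
  network@flow[first] - off
}

#' @rdname excessFlow
#' @export
isSafeAllFDs <- function(network, path) {
  excessFlow(network, path) > 0
}

#' Y-to-V contraction
#'
#' Repeatedly contracts an edge (u,v) when v has in-degree one or u has
#' out-degree one (the source and sink themselves are never merged away),
#' accumulating for each contracted edge the original node sequence it
#' represents. Merges are restricted so that every contracted edge stays an
#' extended unitig: a path whose interior is a block of in-degree-one nodes
#' followed by a block of out-degree-one nodes. Any solution path that uses
#' the edge between the two blocks is forced through the whole unitig, which
#' is why extended unitigs are safe for every flow decomposition; an
#' unrestricted merge order could interleave the blocks and break this
#' guarantee. Contraction preserves the (minimum) flow decompositions.
#'
#' Contraction can produce parallel edges (two extended unitigs sharing both
#' endpoints); the contracted [FlowNetwork] is then a multigraph and its paths
#' must be addressed by edge indices, see [expandPath()].
#'
#' @param network A valid [FlowNetwork].
#' @return A [ContractionMap].
#' @examples
#' cm <- contractYtoV(instanceNetwork(gadget("crossing")))
#' contractedEdgePaths(cm)
#' @export
contractYtoV <- function(network) {
  .stopifInvalid(network)
  from <- network@from
  to <- network@to
  flow <- network@flow
  epaths <- mapply(function(u, v) c(u, v), from, to, SIMPLIFY = FALSE)
  # interior block sizes per edge: in-degree-one prefix, out-degree-one suffix
  inLen <- integer(length(from))
  outLen <- integer(length(from))
  s <- network@source
  t <- network@sink
  repeat {
    done <- TRUE
    ord <- order(from, to) # deterministic scan order
    for (e in ord) {
      u <- from[e]; v <- to[e]
      # absorb v forward: v joins the in-degree-one prefix of the new edges,
      # so edge e must not yet have an out-degree-one suffix
      if (v != t && v != s && sum(to == v) == 1L && outLen[e] == 0L) {
        for (o in which(from == v)) {
          from[o] <- u
          epaths[[o]] <- c(epaths[[e]], epaths[[o]][-1L])
          inLen[o] <- inLen[e] + 1L + inLen[o]
        }
        keep <- -e
        from <- from[keep]; to <- to[keep]; flow <- flow[keep]
        epaths <- epaths[keep]; inLen <- inLen[keep]; outLen <- outLen[keep]
        done <- FALSE
        break
      }
      # absorb u backward: u joins the out-degree-one suffix, so edge e must
      # not have an in-degree-one prefix
      if (u != s && u != t && sum(from == u) == 1L && inLen[e] == 0L) {
        for (o in which(to == u)) {
          to[o] <- v
          epaths[[o]] <- c(epaths[[o]], epaths[[e]][-1L])
          outLen[o] <- outLen[o] + 1L + outLen[e]
        }
        keep <- -e
        from <- from[keep]; to <- to[keep]; flow <- flow[keep]
        epaths <- epaths[keep]; inLen <- inLen[keep]; outLen <- outLen[keep]
        done <- FALSE
        break
      }
    }
    if (done) break
  }
  ord <- order(from, to, vapply(epaths, .pathKey, character(1)))
  contracted <- new("FlowNetwork",
    nodes = sort(unique(c(from[ord], to[ord]))),
    from = from[ord], to = to[ord], flow = flow[ord],
    source = s, sink = t,
    graphId = network@graphId)
  new("ContractionMap", original = network, contracted = contracted,
      edgePaths = epaths[ord])
}

#' Expand a contracted-graph path to original coordinates
#'
#' Concatenates the original node sequences stored for each contracted edge,
#' deduplicating the shared junction nodes. Because contraction can create
#' parallel edges (whose node sequences in the contracted graph coincide),
#' paths may be given as `list(edges = ...)` edge-index sequences; a plain
#' node sequence is accepted whenever it is unambiguous.
#'
#' @param cmap A [ContractionMap].
#' @param path A path of the contracted network: integer node sequence or
#'   `list(edges = ...)`.
#' @return Integer vector: the corresponding path of the original network.
#' @export
expandPath <- function(cmap, path) {
  p <- .asPath(cmap@contracted, path)
  out <- cmap@edgePaths[[p$edges[1L]]]
  for (e in p$edges[-1L]) {
    out <- c(out, cmap@edgePaths[[e]][-1L])
  }
  out
}

#' Funnel test
#'
#' A funnel is a flow graph with a unique flow decomposition; after full
#' Y-to-V contraction every remaining edge goes directly from the source to
#' the sink, so all maximal safe paths can be reported without any integer
#' program.
#'
#' @param network A valid [FlowNetwork].
#' @return `TRUE` iff the network is a funnel.
#' @export
isFunnel <- function(network) {
  cm <- contractYtoV(network)
  all(cm@contracted@from == network@source &
      cm@contracted@to == network@sink)
}

#' Greedy flow decomposition
#'
#' Produces a valid (not necessarily minimum) flow decomposition by repeatedly
#' following, from the source, the out-edge with maximum residual flow (ties
#' broken by head node identifier, then edge position), assigning the path the
#' minimum residual flow along it and subtracting. The superposition of the
#' returned weighted paths equals the flow exactly. Used as the scan skeleton
#' for the safe-for-all-FDs baseline.
#'
#' @param network A valid [FlowNetwork].
#' @return A [WeightedDecomposition].
#' @examples
#' greedyFlowDecomposition(instanceNetwork(gadget("crossing")))
#' @export
greedyFlowDecomposition <- function(network) {
  .stopifInvalid(network)
  residual <- network@flow
  paths <- list()
  epaths <- list()
  weights <- integer()
  while (any(residual > 0)) {
    v <- network@source
    edges <- integer()
    while (v != network@sink) {
      out <- .outEdges(network, v)
      out <- out[residual[out] > 0]
      stopifnot(length(out) > 0)
      pick <- out[order(-residual[out], network@to[out], out)][1L]
      edges <- c(edges, pick)
      v <- network@to[pick]
    }
    w <- min(residual[edges])
    residual[edges] <- residual[edges] - w
    paths[[length(paths) + 1L]] <- .nodesFromEdges(network, edges)
    epaths[[length(epaths) + 1L]] <- edges
    weights <- c(weights, as.integer(w))
  }
  new("WeightedDecomposition", paths = paths, edgePaths = epaths,
      weights = weights)
}

# superposition of a weighted decomposition as an edge-flow vector
.superpose <- function(network, decomposition) {
  f <- numeric(length(network@from))
  for (i in seq_along(decomposition@edgePaths)) {
    e <- decomposition@edgePaths[[i]]
    f[e] <- f[e] + decomposition@weights[i]
  }
  f
}
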