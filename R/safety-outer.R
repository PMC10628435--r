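# Outer algorithms producing all maximal safe paths. Both work over windows
# P_i[a,b] of the paths of one fixed minimum decomposition (any minimum
# decomposition contains every maximal safe path as a window of one of its
# paths). Windows are kept as edge-index sequences so they remain well defined
# on contracted multigraphs.

# window bookkeeping: a window of mfd path i covering edge positions a..b
.windowEdges <- function(epaths, w) epaths[[w$i]][w$a:w$b]

.edgeKey <- function(e) paste(e, collapse = ",")

# canonicalize (paths, provenance) pairs jointly; paths are node sequences
.canonicalizeReport <- function(paths, provenance) {
  if (!length(paths)) return(list(paths = list(), provenance = character()))
  keys <- vapply(paths, .pathKey, character(1))
  keep1 <- !duplicated(keys)
  paths <- paths[keep1]
  provenance <- provenance[keep1]
  keep2 <- vapply(seq_along(paths), function(i) {
    !any(vapply(seq_along(paths), function(j) {
      j != i && .isSubpath(paths[[i]], paths[[j]])
    }, logical(1)))
  }, logical(1))
  paths <- paths[keep2]
  provenance <- provenance[keep2]
  ord <- .orderPaths(paths)
  list(paths = paths[ord], provenance = provenance[ord])
}

# Top-down trimming over a trimming core. Returns edge-list windows found
# safe, with provenance, call counts and a timeout flag; coordinates are those
# of `network` (possibly a contracted multigraph).
.trimCore <- function(network, k, mfd, constraints = NULL, timeBudget = Inf) {
  epaths <- mfd@edgePaths
  core <- lapply(seq_along(epaths), function(i) {
    list(i = i, a = 1L, b = length(epaths[[i]]))
  })
  safeEdges <- list()
  provenance <- character()
  calls <- 0L
  left <- timeBudget
  t0 <- proc.time()[["elapsed"]]
  while (length(core)) {
    # deduplicate windows by edge sequence; drop windows contained in an
    # already-reported safe path (they cannot be maximal safe)
    windows <- lapply(core, function(w) .windowEdges(epaths, w))
    keep <- !duplicated(vapply(windows, .edgeKey, character(1)))
    core <- core[keep]; windows <- windows[keep]
    contained <- vapply(windows, function(e) {
      any(vapply(safeEdges, function(s) .isSubpath(e, s), logical(1)))
    }, logical(1))
    core <- core[!contained]; windows <- windows[!contained]
    if (!length(core)) break

    pre <- excessFlowPrefilter(network,
                               lapply(windows, function(e) list(edges = e)))
    for (p in pre$flowSafe) {
      safeEdges <- c(safeEdges, list(p$edges))
      provenance <- c(provenance, "excess_flow")
    }
    unsafeKeys <- character()
    if (length(pre$toTest)) {
      gs <- getSafe(network, k, pre$toTest, constraints,
                    timeBudget = left - (proc.time()[["elapsed"]] - t0))
      calls <- calls + gs$calls
      if (gs$timedOut) {
        return(list(safeEdges = safeEdges, provenance = provenance,
                    calls = calls, timedOut = TRUE))
      }
      for (p in gs$safe) {
        safeEdges <- c(safeEdges, list(p$edges))
        provenance <- c(provenance, "ilp")
      }
      unsafeKeys <- vapply(gs$unsafe, function(p) .edgeKey(p$edges),
                           character(1))
    }
    # trim each unsafe window by one node on each side and recurse
    nxt <- list()
    for (idx in seq_along(core)) {
      w <- core[[idx]]
      if (!(.edgeKey(windows[[idx]]) %in% unsafeKeys)) next
      if (w$b - w$a >= 1L) { # children still have >= 1 edge
        nxt <- c(nxt, list(list(i = w$i, a = w$a + 1L, b = w$b),
                           list(i = w$i, a = w$a, b = w$b - 1L)))
      }
    }
    core <- nxt
  }
  list(safeEdges = safeEdges, provenance = provenance, calls = calls,
       timedOut = FALSE)
}

# Two-pointer scan over one edge path. `testFun(edges)` decides safety of a
# window and returns TRUE/FALSE, or NA on timeout. Emits maximal safe windows.
.twoPointerPath <- function(edges, testFun) {
  L <- length(edges)
  out <- list()
  a <- 1L
  b <- 1L
  repeat {
    while (b < L) {
      ok <- testFun(edges[a:(b + 1L)])
      if (is.na(ok)) return(NULL)
      if (!ok) break
      b <- b + 1L
    }
    out <- c(out, list(edges[a:b]))
    if (b == L) break
    repeat {
      a <- a + 1L
      ok <- testFun(edges[a:(b + 1L)])
      if (is.na(ok)) return(NULL)
      if (ok) break
    }
    b <- b + 1L
  }
  out
}

.twoPointerCore <- function(network, k, mfd, constraints = NULL,
                            timeBudget = Inf) {
  calls <- 0L
  t0 <- proc.time()[["elapsed"]]
  timedOut <- FALSE
  testFun <- function(edges) {
    if (excessFlow(network, list(edges = edges)) > 0) return(TRUE)
    left <- timeBudget - (proc.time()[["elapsed"]] - t0)
    gs <- getSafe(network, k, list(list(edges = edges)), constraints,
                  timeBudget = left)
    calls <<- calls + gs$calls
    if (gs$timedOut) return(NA)
    length(gs$safe) == 1L
  }
  safeEdges <- list()
  for (i in seq_along(mfd@edgePaths)) {
    wins <- .twoPointerPath(mfd@edgePaths[[i]], testFun)
    if (is.null(wins)) {
      return(list(safeEdges = safeEdges, provenance = character(),
                  calls = calls, timedOut = TRUE))
    }
    safeEdges <- c(safeEdges, wins)
  }
  prov <- vapply(safeEdges, function(e) {
    if (excessFlow(network, list(edges = e)) > 0) "excess_flow" else "ilp"
  }, character(1))
  list(safeEdges = safeEdges, provenance = prov, calls = calls,
       timedOut = FALSE)
}

.buildReport <- function(network, core, mode) {
  paths <- lapply(core$safeEdges, function(e) .nodesFromEdges(network, e))
  cr <- .canonicalizeReport(paths, core$provenance)
  new("SafetyReport", graphId = network@graphId, paths = cr$paths,
      provenance = cr$provenance, mode = mode,
      ilpCalls = as.integer(core$calls),
      timedOut = isTRUE(core$timedOut), wallTime = NA_real_)
}

#' Maximal safe paths from a trimming core
#'
#' Top-down outer algorithm. The paths of one minimum decomposition form the
#' initial trimming core: every unreported maximal safe path is a window of a
#' core member. Each round resolves the current windows with the excess-flow
#' prefilter and the recursive group test; safe windows are reported as
#' maximal safe, and every unsafe window spawns the two windows trimmed by one
#' node on the left and on the right (duplicates, sub-edge windows and windows
#' contained in an already-reported safe path are dropped). Single-edge
#' windows have positive excess flow, so the recursion terminates.
#'
#' @param network A valid [FlowNetwork].
#' @param k The verified minimum decomposition size.
#' @param mfd A minimum [WeightedDecomposition] of `network` (see
#'   [findMinimumK()]).
#' @param constraints Optional subpath constraints.
#' @param timeBudget Wall-clock budget in seconds.
#' @return A [SafetyReport] (mode `"mfd_safe"`) in the coordinates of
#'   `network`.
#' @examples
#' net <- instanceNetwork(gadget("crossing"))
#' fit <- findMinimumK(net)
#' trimMaximalSafe(net, fit$k, fit$decomposition)
#' @export
trimMaximalSafe <- function(network, k, mfd, constraints = NULL,
                            timeBudget = Inf) {
  t0 <- proc.time()[["elapsed"]]
  core <- .trimCore(network, k, mfd, constraints, timeBudget)
  rep <- .buildReport(network, core, "mfd_safe")
  rep@wallTime <- proc.time()[["elapsed"]] - t0
  rep
}

#' Maximal safe paths by the two-pointer scan
#'
#' Baseline outer algorithm: for each path of the minimum decomposition, slide
#' a window with left and right pointers, testing one window at a time (excess
#' flow first, then a singleton group test). The window is extended right
#' while safe; on failure the current window is reported as maximal and the
#' left pointer advances. Produces the same canonical safe set as
#' [trimMaximalSafe()] but generally needs more MILP calls, which is what the
#' group-testing trimming algorithm is designed to save.
#'
#' @inheritParams trimMaximalSafe
#' @return A [SafetyReport] (mode `"mfd_safe"`).
#' @export
twoPointerMaximalSafe <- function(network, k, mfd, constraints = NULL,
                                  timeBudget = Inf) {
  t0 <- proc.time()[["elapsed"]]
  core <- .twoPointerCore(network, k, mfd, constraints, timeBudget)
  rep <- .buildReport(network, core, "mfd_safe")
  rep@wallTime <- proc.time()[["elapsed"]] - t0
  rep
}

#' Maximal safe paths for all flow decompositions
#'
#' The safe-for-all-FDs baseline: a two-pointer scan over the paths of a
#' greedy flow decomposition using the excess-flow characterization as the
#' inner test (paths with positive excess flow are safe for every flow
#' decomposition, of any size). No integer program is used.
#'
#' @param network A valid [FlowNetwork].
#' @return A [SafetyReport] (mode `"all_fd"`, provenance `"excess_flow"`).
#' @examples
#' safePathsAllFDs(instanceNetwork(gadget("g4")))
#' @export
safePathsAllFDs <- function(network) {
  .stopifInvalid(network)
  t0 <- proc.time()[["elapsed"]]
  fd <- greedyFlowDecomposition(network)
  testFun <- function(edges) excessFlow(network, list(edges = edges)) > 0
  safeEdges <- list()
  for (i in seq_along(fd@edgePaths)) {
    safeEdges <- c(safeEdges, .twoPointerPath(fd@edgePaths[[i]], testFun))
  }
  core <- list(safeEdges = safeEdges,
               provenance = rep("excess_flow", length(safeEdges)),
               calls = 0L, timedOut = FALSE)
  rep <- .buildReport(network, core, "all_fd")
  rep@wallTime <- proc.time()[["elapsed"]] - t0
  rep
}

#' Extended unitigs
#'
#' The weakest safe baseline: the node paths represented by the edges of the
#' Y-to-V contracted graph (maximal paths formed by a prefix of in-degree-one
#' nodes followed by out-degree-one nodes), canonicalized.
#'
#' @param network A valid [FlowNetwork].
#' @return A [SafetyReport] (mode `"eunitigs"`).
#' @export
extendedUnitigs <- function(network) {
  .stopifInvalid(network)
  t0 <- proc.time()[["elapsed"]]
  cm <- contractYtoV(network)
  paths <- canonicalizePaths(cm@edgePaths)
  new("SafetyReport", graphId = network@graphId, paths = paths,
      provenance = rep("eunitig", length(paths)), mode = "eunitigs",
      ilpCalls = 0L, timedOut = FALSE,
      wallTime = proc.time()[["elapsed"]] - t0)
}

# Peel the source-to-sink extended unitigs off a (simple) flow network.
# Every flow decomposition path that uses such a unitig's pivot edge is the
# unitig itself, so each one is a member of every minimum decomposition: it
# is reported as a maximal safe path and its flow is subtracted from the
# network. Returns the safe paths and the residual network (NULL when the
# graph was a funnel and nothing remains).
.peelStUnitigs <- function(network) {
  cm <- contractYtoV(network)
  cnet <- cm@contracted
  stEdges <- which(cnet@from == network@source & cnet@to == network@sink)
  if (!length(stEdges)) {
    return(list(safePaths = list(), residual = network))
  }
  flow <- network@flow
  safe <- list()
  for (e in stEdges) {
    p <- cm@edgePaths[[e]]
    idx <- .edgesFromNodes(network, p)
    flow[idx] <- flow[idx] - cnet@flow[e]
    safe <- c(safe, list(p))
  }
  keep <- flow > 0
  if (!any(keep)) {
    return(list(safePaths = safe, residual = NULL))
  }
  residual <- new("FlowNetwork",
                  nodes = sort(unique(c(network@from[keep],
                                        network@to[keep]))),
                  from = network@from[keep], to = network@to[keep],
                  flow = flow[keep], source = network@source,
                  sink = network@sink, graphId = network@graphId)
  list(safePaths = safe, residual = residual)
}

#' All maximal safe paths for minimum flow decompositions
#'
#' The full pipeline: validate; Y-to-V contract; report the source-to-sink
#' extended unitigs as safe without any solver call and peel their flow off
#' the graph (for a funnel this resolves the whole instance, so no integer
#' program is ever built); then find the minimum decomposition size of the
#' residual graph and run the chosen outer algorithm on it; finally
#' canonicalize all reported paths. If the time budget is exhausted at any
#' stage, partial results are discarded and the safe-for-all-FDs baseline is
#' returned instead (mode `"all_fd_fallback"`).
#'
#' Window trimming and the group tests work at original node granularity
#' (maximal safe paths can end inside an extended unitig, at the boundary
#' between its in-branching prefix and out-branching suffix, so windows of
#' contracted edges cannot express every candidate). Contraction is used for
#' the peeling shortcut above and the unitig baseline. When subpath
#' constraints are supplied the peeling is skipped as well, because
#' constraint paths may overlap the peeled unitigs.
#'
#' @param network A valid [FlowNetwork] without parallel edges.
#' @param algorithm Outer algorithm: `"trim"` (group-testing trimming core,
#'   the default) or `"two_pointer"`.
#' @param constraints Optional list of subpath constraints (node sequences).
#' @param timeBudget Wall-clock budget in seconds for this graph (default 120).
#' @param contract Set `FALSE` to skip the contraction shortcut (used to
#'   audit that it leaves the results unchanged).
#' @return A [SafetyReport] in original node coordinates.
#' @examples
#' findAllMaximalSafeMFD(instanceNetwork(gadget("crossing")))
#' @export
findAllMaximalSafeMFD <- function(network,
                                  algorithm = c("trim", "two_pointer"),
                                  constraints = NULL, timeBudget = 120,
                                  contract = TRUE) {
  algorithm <- match.arg(algorithm)
  .stopifInvalid(network)
  if (anyDuplicated(paste(network@from, network@to))) {
    stop("the safety pipeline expects a simple graph (no parallel edges)")
  }
  t0 <- proc.time()[["elapsed"]]
  elapsed <- function() proc.time()[["elapsed"]] - t0
  fallback <- function(calls) {
    rep <- safePathsAllFDs(network)
    rep@mode <- "all_fd_fallback"
    rep@provenance <- rep("fallback_all_fd", length(rep@paths))
    rep@ilpCalls <- as.integer(calls)
    rep@timedOut <- TRUE
    rep@wallTime <- elapsed()
    rep
  }

  safePathsPre <- list()
  provPre <- character()
  work <- network
  if (contract && !length(constraints)) {
    peel <- .peelStUnitigs(network)
    safePathsPre <- peel$safePaths
    provPre <- rep("funnel", length(safePathsPre))
    if (is.null(peel$residual)) {
      cr <- .canonicalizeReport(safePathsPre, provPre)
      return(new("SafetyReport", graphId = network@graphId,
                 paths = cr$paths, provenance = cr$provenance,
                 mode = "mfd_safe", ilpCalls = 0L, timedOut = FALSE,
                 wallTime = elapsed()))
    }
    work <- peel$residual
  }

  kres <- findMinimumK(work, constraints, timeBudget - elapsed())
  if (kres$status != "optimal") return(fallback(kres$calls))
  outer <- if (algorithm == "trim") .trimCore else .twoPointerCore
  core <- outer(work, kres$k, kres$decomposition, constraints,
                timeBudget - elapsed())
  if (core$timedOut) return(fallback(kres$calls + core$calls))

  paths <- c(safePathsPre,
             lapply(core$safeEdges, function(e) .nodesFromEdges(work, e)))
  prov <- c(provPre, core$provenance)
  cr <- .canonicalizeReport(paths, prov)
  new("SafetyReport", graphId = network@graphId, paths = cr$paths,
      provenance = cr$provenance, mode = "mfd_safe",
      ilpCalls = as.integer(kres$calls + core$calls), timedOut = FALSE,
      wallTime = elapsed())
}
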