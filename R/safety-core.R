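# Inner safety machinery: the group safety test. A path is safe when it is a
# contiguous subpath of some solution path of EVERY minimum flow
# decomposition. For a set of candidate paths, one MILP solve at the fixed
# minimum cardinality k* decides as much as possible in a single call: each
# candidate gets a binary avoidance indicator that may be 1 only if no slot
# uses all of the candidate's edges, and the objective maximizes the number of
# simultaneously avoided candidates. Avoided candidates are unsafe; an optimum
# of zero certifies that every candidate is safe.

#' Add avoidance indicators for a set of tested paths
#'
#' Extends a feasible k-path decomposition model with one binary indicator per
#' tested path P = (v1..vl): for every slot i the constraint
#' `x[v1v2,i] + ... + x[v(l-1)vl,i] <= (l-1) - gamma_P` forces the indicator
#' to 0 whenever slot i contains P, and the objective becomes
#' `maximize sum_P gamma_P`. Because solution paths do not repeat nodes, a
#' slot contains P exactly when it uses all `l-1` edges of P.
#'
#' @param model A model from [buildFdModel()] at the minimum cardinality.
#' @param paths List of tested paths (node sequences or `list(edges = ...)`),
#'   each with at least one edge. Duplicates are merged with a warning.
#' @return The augmented model; element `gammaIdx` maps tested paths (in the
#'   deduplicated input order, element `testedPaths`) to variable columns.
#' @export
addSafetyLayer <- function(model, paths) {
  stopifnot(length(paths) > 0)
  epaths <- lapply(paths, function(p) .asPath(model$network, p)$edges)
  keys <- vapply(epaths, function(e) paste(e, collapse = ","), character(1))
  if (anyDuplicated(keys)) {
    warning("duplicate tested paths merged before model build")
    epaths <- epaths[!duplicated(keys)]
  }
  np <- length(epaths)
  nv <- model$nv + np
  gammaIdx <- model$nv + seq_len(np)
  A <- cbind(model$A, matrix(0, nrow = nrow(model$A), ncol = np))
  sense <- model$sense
  rhs <- model$rhs
  newRows <- list()
  for (p in seq_len(np)) {
    edges <- epaths[[p]]
    for (i in seq_len(model$k)) {
      r <- numeric(nv)
      r[model$xIdx[i, edges]] <- 1
      r[gammaIdx[p]] <- 1
      newRows[[length(newRows) + 1L]] <- r
      sense <- c(sense, -1L)
      rhs <- c(rhs, length(edges))
    }
  }
  model$A <- rbind(A, do.call(rbind, newRows))
  model$sense <- sense
  model$rhs <- rhs
  model$nv <- nv
  model$gammaIdx <- gammaIdx
  model$testedPaths <- epaths
  obj <- numeric(nv)
  obj[gammaIdx] <- 1
  model$obj <- obj
  model$maximize <- TRUE
  model
}

#' Group safety test
#'
#' One MILP solve that maximizes the number of tested paths a single minimum
#' flow decomposition can avoid simultaneously. Returns the avoided set N:
#' if N is empty, every tested path is safe; otherwise every member of N is
#' unsafe (avoided by the witness decomposition) and the status of the rest is
#' unknown.
#'
#' @param network A valid [FlowNetwork].
#' @param k The verified minimum decomposition size (safety is defined over
#'   minimum decompositions; the avoidance layer never changes k).
#' @param paths Nonempty list of tested paths.
#' @param constraints Optional subpath constraints (see [buildFdModel()]).
#' @param timeBudget Wall-clock budget in seconds for the solve.
#' @return A list: `status`, `N` (avoided tested paths, as
#'   `list(nodes=, edges=)` pairs), `objective` (`|N|`), `statusMap` (named
#'   `"safe"`/`"unsafe"`/`"unknown"` per tested path), `calls` (always 1).
#' @examples
#' net <- instanceNetwork(gadget("crossing"))
#' groupTest(net, 2, list(c(0L, 1L, 3L), c(3L, 4L, 6L)))$objective # 0
#' @export
groupTest <- function(network, k, paths, constraints = NULL,
                      timeBudget = Inf) {
  model <- buildFdModel(network, k, constraints)
  model <- addSafetyLayer(model, paths)
  out <- solveModel(model, timeBudget = timeBudget)
  tested <- lapply(model$testedPaths, function(e) {
    list(nodes = .nodesFromEdges(network, e), edges = e)
  })
  n <- length(tested)
  if (out$status != "optimal") {
    return(list(status = out$status, N = list(), objective = NA_real_,
                statusMap = rep("unknown", n), tested = tested, calls = 1L))
  }
  gamma <- out$x[model$gammaIdx]
  avoided <- gamma > 0.5
  statusMap <- if (any(avoided)) {
    ifelse(avoided, "unsafe", "unknown")
  } else {
    rep("safe", n)
  }
  list(status = "optimal", N = tested[avoided],
       objective = round(out$objective) + 0, # + 0 normalizes signed zero
       statusMap = statusMap,
       tested = tested, calls = 1L)
}

#' Resolve a set of paths into safe and unsafe
#'
#' The recursive group-testing procedure: run [groupTest()]; if nothing can be
#' avoided, all remaining paths are safe; otherwise the avoided paths are
#' unsafe and the test recurses on the rest. A set containing u unsafe paths
#' is fully resolved in at most u + 1 MILP calls, and in exactly one call when
#' all paths are safe.
#'
#' @inheritParams groupTest
#' @return A list: `safe` and `unsafe` (lists of `list(nodes=, edges=)`),
#'   `unknown` (nonempty only after a timeout), `calls`, `timedOut`.
#' @export
getSafe <- function(network, k, paths, constraints = NULL, timeBudget = Inf) {
  if (!length(paths)) {
    return(list(safe = list(), unsafe = list(), unknown = list(),
                calls = 0L, timedOut = FALSE))
  }
  safe <- list()
  unsafe <- list()
  calls <- 0L
  left <- timeBudget
  remaining <- paths
  repeat {
    t0 <- proc.time()[["elapsed"]]
    gt <- groupTest(network, k, remaining, constraints, timeBudget = left)
    left <- left - (proc.time()[["elapsed"]] - t0)
    calls <- calls + gt$calls
    if (gt$status != "optimal") {
      return(list(safe = safe, unsafe = unsafe, unknown = gt$tested,
                  calls = calls, timedOut = TRUE))
    }
    if (gt$objective == 0) {
      safe <- c(safe, gt$tested)
      break
    }
    unsafe <- c(unsafe, gt$N)
    keep <- gt$statusMap != "unsafe"
    if (!any(keep)) break
    remaining <- lapply(gt$tested[keep], function(p) list(edges = p$edges))
  }
  list(safe = safe, unsafe = unsafe, unknown = list(), calls = calls,
       timedOut = FALSE)
}

#' Excess-flow prefilter
#'
#' Splits a set of candidate paths into those whose excess flow is positive --
#' safe for all flow decompositions and hence for minimum ones, no MILP needed
#' -- and those that still need the group test.
#'
#' @param network A valid [FlowNetwork].
#' @param paths List of candidate paths.
#' @return A list with elements `flowSafe` and `toTest` (both lists of
#'   `list(nodes=, edges=)`); their union is the input.
#' @export
excessFlowPrefilter <- function(network, paths) {
  resolved <- lapply(paths, function(p) .asPath(network, p))
  pos <- vapply(resolved, function(p) {
    excessFlow(network, list(edges = p$edges)) > 0
  }, logical(1))
  list(flowSafe = resolved[pos], toTest = resolved[!pos])
}
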