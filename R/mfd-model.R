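# The flow-decomposition MILP. A model is a plain list: a dense constraint
# system plus index maps from (slot, edge) to variable columns. Solutions are
# k source-to-sink paths (binary edge indicators x[i,e] obeying per-node
# balance) with integer weights w[i] >= 1 whose superposition equals the flow.
# The bilinear superposition sum_i x[i,e] * w[i] = f_e is linearized with
# product variables pi[i,e] and big-M bound W = max edge flow (no path can
# carry more weight than the flow of any edge it uses).

#' Build the flow-decomposition MILP for k paths
#'
#' Constructs the integer program whose feasible points are the flow
#' decompositions of `network` into exactly `k` weighted source-to-sink paths:
#' per-slot path-balance constraints on binary edge variables, integer weight
#' variables, linearized superposition constraints, and (optionally) subpath
#' constraints requiring each given path to appear contiguously inside at
#' least one solution path.
#'
#' @param network A valid [FlowNetwork] (parallel edges permitted).
#' @param k Number of path slots (>= 1).
#' @param constraints Optional list of subpath constraints, each an integer
#'   node sequence (or `list(edges = ...)`) that must be a path of the
#'   network.
#' @return A model object (opaque list) for [solveModel()].
#' @examples
#' net <- instanceNetwork(gadget("crossing"))
#' m <- buildFdModel(net, k = 2)
#' solveModel(m)$status
#' @export
buildFdModel <- function(network, k, constraints = NULL) {
  stopifnot(k >= 1)
  m <- length(network@from)
  W <- max(network@flow)
  nx <- k * m
  nv <- 2L * nx + k
  xIdx <- matrix(seq_len(nx), nrow = k, byrow = TRUE)
  wIdx <- nx + seq_len(k)
  piIdx <- matrix(nx + k + seq_len(nx), nrow = k, byrow = TRUE)

  rows <- list()
  sense <- integer()
  rhs <- numeric()
  addRow <- function(cols, coef, sns, b) {
    r <- numeric(nv)
    r[cols] <- coef
    rows[[length(rows) + 1L]] <<- r
    sense[length(sense) + 1L] <<- sns
    rhs[length(rhs) + 1L] <<- b
  }

  for (i in seq_len(k)) {
    for (v in network@nodes) {
      inc <- .inEdges(network, v)
      out <- .outEdges(network, v)
      b <- if (v == network@sink) 1 else if (v == network@source) -1 else 0
      addRow(c(xIdx[i, inc], xIdx[i, out]),
             c(rep(1, length(inc)), rep(-1, length(out))), 0L, b)
    }
  }
  for (e in seq_len(m)) {
    addRow(piIdx[, e], rep(1, k), 0L, network@flow[e])
  }
  for (i in seq_len(k)) {
    for (e in seq_len(m)) {
      addRow(c(piIdx[i, e], xIdx[i, e]), c(1, -W), -1L, 0)   # pi <= W x
      addRow(c(piIdx[i, e], wIdx[i]), c(1, -1), -1L, 0)      # pi <= w
      addRow(c(piIdx[i, e], wIdx[i], xIdx[i, e]),
             c(1, -1, -W), 1L, -W)                           # pi >= w - W(1-x)
    }
  }

  rIdx <- NULL
  cpaths <- list()
  if (length(constraints)) {
    cpaths <- lapply(constraints, function(p) .asPath(network, p)$edges)
    ell <- length(cpaths)
    rIdx <- matrix(nv + seq_len(k * ell), nrow = k, byrow = TRUE)
    nvNew <- nv + k * ell
    rows <- lapply(rows, function(r) c(r, numeric(k * ell)))
    nv <- nvNew
    addRow <- function(cols, coef, sns, b) {
      r <- numeric(nv)
      r[cols] <- coef
      rows[[length(rows) + 1L]] <<- r
      sense[length(sense) + 1L] <<- sns
      rhs[length(rhs) + 1L] <<- b
    }
    for (j in seq_len(ell)) {
      nEdges <- length(cpaths[[j]])
      for (i in seq_len(k)) {
        addRow(c(xIdx[i, cpaths[[j]]], rIdx[i, j]),
               c(rep(1, nEdges), -nEdges), 1L, 0)
      }
      addRow(rIdx[, j], rep(1, k), 1L, 1)
    }
  }

  structure(list(
    network = network, k = as.integer(k), nv = nv, W = W,
    xIdx = xIdx, wIdx = wIdx, piIdx = piIdx, rIdx = rIdx,
    constraintPaths = cpaths,
    gammaIdx = integer(0), testedPaths = list(),
    A = do.call(rbind, rows), sense = sense, rhs = rhs,
    obj = numeric(nv), maximize = FALSE
  ), class = "fdModel")
}

#' Solve a flow-decomposition model
#'
#' Runs the configured MILP backend on the model. The bundled backend
#' (`"bb"`) is a deterministic single-threaded branch-and-bound solver over a
#' two-phase simplex; any backend must accept the same dense model and report
#' `optimal`, `infeasible` or `timeout`.
#'
#' @param model A model from [buildFdModel()] (possibly extended by
#'   [addSafetyLayer()]).
#' @param timeBudget Wall-clock budget in seconds; a model given a budget of 0
#'   reports `timeout` immediately.
#' @param backend Name of the solver backend (option `flowsafety.solver`).
#' @return A list: `status` (`"optimal"`, `"infeasible"`, `"timeout"`),
#'   `x` (variable assignment when optimal), `objective`, `nodes`
#'   (branch-and-bound nodes), `wallTime` (seconds).
#' @export
solveModel <- function(model, timeBudget = Inf,
                       backend = getOption("flowsafety.solver", "bb")) {
  if (!identical(backend, "bb")) {
    stop("unknown solver backend '", backend, "' (configured backends: bb)")
  }
  if (timeBudget <= 0) {
    return(list(status = "timeout", x = numeric(0), objective = NA_real_,
                nodes = 0, wallTime = 0))
  }
  t0 <- proc.time()[["elapsed"]]
  res <- milp_solve_cpp(model$obj, model$A, as.integer(model$sense),
                        model$rhs, model$lb %||% .modelLb(model),
                        model$ub %||% .modelUb(model),
                        .modelIsInt(model), model$maximize,
                        as.double(min(timeBudget, 1e9)),
                        1000000L, 5e8)
  res$wallTime <- proc.time()[["elapsed"]] - t0
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.modelLb <- function(model) {
  lb <- numeric(model$nv)
  lb[model$wIdx] <- 1
  lb
}

.modelUb <- function(model) {
  ub <- numeric(model$nv)
  ub[as.vector(model$xIdx)] <- 1
  ub[model$wIdx] <- model$W
  ub[as.vector(model$piIdx)] <- model$W
  if (!is.null(model$rIdx)) ub[as.vector(model$rIdx)] <- 1
  if (length(model$gammaIdx)) ub[model$gammaIdx] <- 1
  ub
}

.modelIsInt <- function(model) {
  it <- rep(FALSE, model$nv)
  it[as.vector(model$xIdx)] <- TRUE
  it[model$wIdx] <- TRUE
  if (!is.null(model$rIdx)) it[as.vector(model$rIdx)] <- TRUE
  if (length(model$gammaIdx)) it[model$gammaIdx] <- TRUE
  it
}

#' Extract the weighted paths from a solved model
#'
#' Traces, for each path slot, the edges whose binary indicators are 1 from
#' the source to the sink, and reads off the integer weight. The extracted
#' decomposition is asserted to superpose to the flow exactly.
#'
#' @param model A model from [buildFdModel()].
#' @param outcome An optimal result from [solveModel()].
#' @return A [WeightedDecomposition].
#' @export
extractDecomposition <- function(model, outcome) {
  stopifnot(identical(outcome$status, "optimal"))
  net <- model$network
  x <- outcome$x
  paths <- list()
  epaths <- list()
  weights <- integer(model$k)
  for (i in seq_len(model$k)) {
    chosen <- which(x[model$xIdx[i, ]] > 0.5)
    v <- net@source
    edges <- integer()
    while (v != net@sink) {
      nxt <- chosen[net@from[chosen] == v]
      if (length(nxt) != 1L) {
        stop("solution indicators of slot ", i,
             " do not form a single source-to-sink path")
      }
      edges <- c(edges, nxt)
      v <- net@to[nxt]
    }
    if (length(edges) != length(chosen)) {
      stop("solution indicators of slot ", i, " contain off-path edges")
    }
    paths[[i]] <- .nodesFromEdges(net, edges)
    epaths[[i]] <- edges
    weights[i] <- as.integer(round(x[model$wIdx[i]]))
  }
  dec <- new("WeightedDecomposition", paths = paths, edgePaths = epaths,
             weights = weights)
  if (!all(.superpose(net, dec) == net@flow)) {
    stop("extracted decomposition does not superpose to the flow")
  }
  dec
}

#' Lower bound on the minimum number of decomposition paths
#'
#' Every decomposition path uses exactly one out-edge of the source and one
#' in-edge of the sink, and every (positive-flow) such edge must be covered,
#' so the larger of the two degree counts never exceeds the true minimum.
#'
#' @param network A valid [FlowNetwork].
#' @return A positive integer.
#' @export
lowerBoundK <- function(network) {
  max(1L, length(.outEdges(network, network@source)),
      length(.inEdges(network, network@sink)))
}

#' Find a minimum flow decomposition
#'
#' Searches k = `lowerBoundK(network)`, k+1, ... until the k-path model (with
#' any subpath constraints) is feasible, and returns the first optimum. With
#' constraints present the minimum is over constrained decompositions only.
#'
#' @inheritParams buildFdModel
#' @param timeBudget Cumulative wall-clock budget in seconds across all solver
#'   calls.
#' @return A list: `status` (`"optimal"` or `"timeout"`), `k`, `decomposition`
#'   (a [WeightedDecomposition]), `calls` (number of MILP solves).
#' @examples
#' findMinimumK(instanceNetwork(gadget("three_path")))$k # 3
#' @export
findMinimumK <- function(network, constraints = NULL, timeBudget = Inf) {
  .stopifInvalid(network)
  kmax <- sum(network@flow[.outEdges(network, network@source)])
  calls <- 0L
  left <- timeBudget
  for (k in lowerBoundK(network):kmax) {
    model <- buildFdModel(network, k, constraints)
    t0 <- proc.time()[["elapsed"]]
    out <- solveModel(model, timeBudget = left)
    left <- left - (proc.time()[["elapsed"]] - t0)
    calls <- calls + 1L
    if (out$status == "timeout") {
      return(list(status = "timeout", k = NA_integer_, decomposition = NULL,
                  calls = calls))
    }
    if (out$status == "optimal") {
      return(list(status = "optimal", k = k,
                  decomposition = extractDecomposition(model, out),
                  calls = calls, model = model))
    }
  }
  stop("no feasible decomposition up to k = ", kmax,
       " (unsatisfiable subpath constraints?)")
}
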