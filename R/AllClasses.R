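#' @useDynLib flowsafety, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
NULL

#' FlowNetwork: a DAG with integer edge flows
#'
#' A directed acyclic flow network with a unique source and a unique sink.
#' Every edge carries a positive integer flow value (read-abundance counts in
#' the splice-graph interpretation: nodes are exons, edges are splice
#' junctions). Parallel edges are permitted; they arise from Y-to-V
#' contraction, where two contracted edges between the same pair of nodes
#' represent different extended unitigs of the original graph.
#'
#' Structural validity (matching slot lengths, node references) is enforced by
#' the class validity method. The domain invariants -- acyclicity, unique
#' source and sink, positive flows, and flow conservation at internal nodes --
#' are checked by [flowViolations()], which reports violations rather than
#' failing, so that deliberately broken networks can be constructed and
#' audited.
#'
#' @slot nodes Integer vector of node identifiers (opaque labels, sorted).
#' @slot from,to Integer vectors defining the edge list (node identifiers).
#' @slot flow Numeric vector of integer-valued edge flows.
#' @slot source,sink Integer scalar node identifiers.
#' @slot graphId Character label, typically from the graph-file header.
#'
#' @seealso [flowNetwork()], [readGraphFile()], [flowViolations()]
#' @export
setClass("FlowNetwork",
  representation(
    nodes = "integer",
    from = "integer",
    to = "integer",
    flow = "numeric",
    source = "integer",
    sink = "integer",
    graphId = "character"
  )
)

setValidity("FlowNetwork", function(object) {
  msg <- character()
  if (length(object@from) != length(object@to) ||
      length(object@from) != length(object@flow)) {
    msg <- c(msg, "edge slots 'from', 'to', 'flow' must have equal length")
  }
  if (length(object@source) != 1L || length(object@sink) != 1L) {
    msg <- c(msg, "'source' and 'sink' must be scalars")
  }
  if (anyDuplicated(object@nodes)) {
    msg <- c(msg, "'nodes' must be unique")
  }
  if (!all(c(object@from, object@to) %in% object@nodes)) {
    msg <- c(msg, "edge endpoints must be listed in 'nodes'")
  }
  if (length(msg)) msg else TRUE
})

#' ContractionMap: result of Y-to-V contraction
#'
#' Couples a contracted [FlowNetwork] with, for each contracted edge, the
#' sequence of original nodes it represents (an extended unitig of the
#' original graph). Expanding every contracted edge and re-superposing the
#' flows reproduces the original network exactly.
#'
#' @slot original,contracted [FlowNetwork] objects.
#' @slot edgePaths List of integer vectors, parallel to the contracted
#'   network's edge list: the original node sequence each edge represents.
#' @seealso [contractYtoV()], [expandPath()]
#' @export
setClass("ContractionMap",
  representation(
    original = "FlowNetwork",
    contracted = "FlowNetwork",
    edgePaths = "list"
  )
)

setValidity("ContractionMap", function(object) {
  if (length(object@edgePaths) != length(object@contracted@from)) {
    return("'edgePaths' must have one entry per contracted edge")
  }
  TRUE
})

#' WeightedDecomposition: weighted source-to-sink paths
#'
#' A flow decomposition: k source-to-sink paths with positive integer weights
#' whose edge-wise superposition equals the flow of the network they
#' decompose.
#'
#' @slot paths List of integer vectors (node sequences, source to sink).
#' @slot edgePaths List of integer vectors (edge indices into the network the
#'   decomposition belongs to); kept alongside the node sequences so that
#'   paths through parallel edges of a contracted graph stay unambiguous.
#' @slot weights Integer vector of path weights, all >= 1.
#' @seealso [findMinimumK()], [greedyFlowDecomposition()]
#' @export
setClass("WeightedDecomposition",
  representation(
    paths = "list",
    edgePaths = "list",
    weights = "integer"
  )
)

setValidity("WeightedDecomposition", function(object) {
  msg <- character()
  if (length(object@paths) != length(object@weights)) {
    msg <- c(msg, "'paths' and 'weights' must have equal length")
  }
  if (length(object@weights) && any(object@weights < 1L)) {
    msg <- c(msg, "all weights must be >= 1")
  }
  if (length(msg)) msg else TRUE
})

#' SafetyReport: maximal safe paths of one flow graph
#'
#' The result of a safety computation on a single flow network: a
#' duplicate-free antichain (under the contiguous-subpath relation) of
#' maximal safe paths in original node coordinates, together with provenance
#' and solver accounting.
#'
#' @slot graphId Character label of the graph.
#' @slot paths List of integer vectors: the maximal safe paths, in
#'   deterministic (lexicographic) order.
#' @slot provenance Character vector parallel to `paths`; one of
#'   `"ilp"`, `"excess_flow"`, `"funnel"`, `"fallback_all_fd"`,
#'   `"eunitig"`.
#' @slot mode `"mfd_safe"`, `"all_fd"`, `"all_fd_fallback"` or `"eunitigs"`.
#' @slot ilpCalls Integer: number of MILP solves performed.
#' @slot timedOut Logical: whether the time budget was exhausted.
#' @slot wallTime Numeric: elapsed seconds.
#' @seealso [findAllMaximalSafeMFD()], [safePathsAllFDs()], [extendedUnitigs()]
#' @export
setClass("SafetyReport",
  representation(
    graphId = "character",
    paths = "list",
    provenance = "character",
    mode = "character",
    ilpCalls = "integer",
    timedOut = "logical",
    wallTime = "numeric"
  )
)

setValidity("SafetyReport", function(object) {
  if (length(object@provenance) != length(object@paths)) {
    return("'provenance' must be parallel to 'paths'")
  }
  TRUE
})

#' GroundTruthInstance: a generated flow network with known transcripts
#'
#' A flow network built by perfectly superposing weighted transcript paths, so
#' that flow conservation holds by construction and the transcripts form a
#' (not necessarily minimum) flow decomposition that serves as ground truth
#' for evaluation.
#'
#' @slot network The [FlowNetwork].
#' @slot transcripts List of integer vectors: source-to-sink transcript paths.
#' @slot abundances Integer vector of transcript abundances (weights).
#' @slot constraints List of integer vectors: optional subpath constraints.
#' @slot seed Integer seed the instance was generated from (NA for gadgets).
#' @slot params List of generator parameters.
#' @seealso [generateInstance()], [gadget()]
#' @export
setClass("GroundTruthInstance",
  representation(
    network = "FlowNetwork",
    transcripts = "list",
    abundances = "integer",
    constraints = "list",
    seed = "integer",
    params = "list"
  )
)

setValidity("GroundTruthInstance", function(object) {
  if (length(object@transcripts) != length(object@abundances)) {
    return("'transcripts' and 'abundances' must have equal length")
  }
  TRUE
})
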