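#' Construct a FlowNetwork
#'
#' Builds a [FlowNetwork] from an edge list. The source and sink are inferred
#' from node degrees unless given explicitly. The constructor enforces only
#' structural consistency; domain invariants can be audited afterwards with
#' [flowViolations()].
#'
#' @param from,to Integer vectors of edge tail/head node identifiers.
#' @param flow Numeric vector of edge flow values.
#' @param nodes Optional integer vector of node identifiers; defaults to the
#'   union of edge endpoints.
#' @param source,sink Optional node identifiers. When `NULL`, the unique node
#'   with no incoming (respectively outgoing) edge is used; an error is raised
#'   when that node is not unique.
#' @param graphId Character label for the graph.
#' @return A [FlowNetwork].
#' @examples
#' net <- flowNetwork(from = c(0L, 1L), to = c(1L, 2L), flow = c(5, 5))
#' flowViolations(net)
#' @export
flowNetwork <- function(from, to, flow, nodes = NULL, source = NULL,
                        sink = NULL, graphId = "g") {
  from <- as.integer(from)
  to <- as.integer(to)
  flow <- as.numeric(flow)
  if (is.null(nodes)) nodes <- sort(unique(c(from, to)))
  nodes <- as.integer(nodes)
  if (is.null(source) || is.null(sink)) {
    src <- setdiff(nodes, to)
    snk <- setdiff(nodes, from)
    if (is.null(source)) {
      if (length(src) != 1L) {
        stop("cannot infer source: ", length(src),
             " nodes without incoming edges")
      }
      source <- src
    }
    if (is.null(sink)) {
      if (length(snk) != 1L) {
        stop("cannot infer sink: ", length(snk),
             " nodes without outgoing edges")
      }
      sink <- snk
    }
  }
  new("FlowNetwork", nodes = nodes, from = from, to = to, flow = flow,
      source = as.integer(source), sink = as.integer(sink),
      graphId = as.character(graphId))
}

#' @rdname flowNetwork
#' @param x A [FlowNetwork].
#' @export
numNodes <- function(x) length(x@nodes)

#' @rdname flowNetwork
#' @export
numEdges <- function(x) length(x@from)

#' @rdname flowNetwork
#' @export
sourceNode <- function(x) x@source

#' @rdname flowNetwork
#' @export
sinkNode <- function(x) x@sink

#' @rdname flowNetwork
#' @export
graphId <- function(x) x@graphId

#' @rdname flowNetwork
#' @export
edgeTable <- function(x) {
  data.frame(from = x@from, to = x@to, flow = x@flow)
}

#' Accessors for decompositions, reports and instances
#'
#' `decompositionPaths()`, `pathWeights()` extract the node-sequence paths and
#' weights of a [WeightedDecomposition]; `safePaths()` the maximal safe paths
#' of a [SafetyReport]; `ilpCalls()` its solver-call counter and
#' `reportMode()` its mode; `instanceNetwork()`, `transcriptPaths()`,
#' `transcriptAbundances()` and `subpathConstraints()` the components of a
#' [GroundTruthInstance].
#'
#' @param x The object.
#' @return The corresponding component.
#' @name decomposition-accessors
#' @export
decompositionPaths <- function(x) x@paths

#' @rdname decomposition-accessors
#' @export
pathWeights <- function(x) x@weights

#' @rdname decomposition-accessors
#' @export
safePaths <- function(x) x@paths

#' @rdname decomposition-accessors
#' @export
ilpCalls <- function(x) x@ilpCalls

#' @rdname decomposition-accessors
#' @export
reportMode <- function(x) x@mode

#' @rdname decomposition-accessors
#' @export
instanceNetwork <- function(x) x@network

#' @rdname decomposition-accessors
#' @export
transcriptPaths <- function(x) x@transcripts

#' @rdname decomposition-accessors
#' @export
transcriptAbundances <- function(x) x@abundances

#' @rdname decomposition-accessors
#' @export
subpathConstraints <- function(x) x@constraints

#' @rdname decomposition-accessors
#' @export
contractedNetwork <- function(x) x@contracted

#' @rdname decomposition-accessors
#' @export
contractedEdgePaths <- function(x) x@edgePaths

.pathLabel <- function(p) paste(p, collapse = " ")

setMethod("show", "FlowNetwork", function(object) {
  cat(sprintf("FlowNetwork '%s': %d nodes, %d edges, source=%d, sink=%d\n",
              object@graphId, length(object@nodes), length(object@from),
              object@source, object@sink))
  n <- length(object@from)
  k <- min(n, 8L)
  if (k > 0) {
    for (i in seq_len(k)) {
      cat(sprintf("  %d -> %d : %g\n", object@from[i], object@to[i],
                  object@flow[i]))
    }
    if (n > k) cat("  ...", n - k, "more edges\n")
  }
})

setMethod("show", "WeightedDecomposition", function(object) {
  cat(sprintf("WeightedDecomposition: %d weighted paths\n",
              length(object@paths)))
  for (i in seq_along(object@paths)) {
    cat(sprintf("  w=%d  %s\n", object@weights[i],
                .pathLabel(object@paths[[i]])))
  }
})

setMethod("show", "SafetyReport", function(object) {
  cat(sprintf(
    "SafetyReport '%s' [mode=%s]: %d maximal safe paths, %d ILP calls%s\n",
    object@graphId, object@mode, length(object@paths), object@ilpCalls,
    if (object@timedOut) " (timed out)" else ""))
  for (i in seq_along(object@paths)) {
    cat(sprintf("  [%s] %s\n", object@provenance[i],
                .pathLabel(object@paths[[i]])))
  }
})

setMethod("show", "ContractionMap", function(object) {
  cat(sprintf(
    "ContractionMap: %d nodes / %d edges -> %d nodes / %d edges\n",
    length(object@original@nodes), length(object@original@from),
    length(object@contracted@nodes), length(object@contracted@from)))
})

setMethod("show", "GroundTruthInstance", function(object) {
  cat(sprintf(
    "GroundTruthInstance '%s': %d transcripts, %d nodes, %d edges\n",
    object@network@graphId, length(object@transcripts),
    length(object@network@nodes), length(object@network@from)))
})

setMethod("length", "WeightedDecomposition", function(x) length(x@paths))
setMethod("length", "SafetyReport", function(x) length(x@paths))
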