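# Path utilities. Paths are node-identifier sequences for the user-facing
# API; the safety machinery additionally carries edge-index sequences so that
# parallel edges of a contracted multigraph stay distinguishable.

.outEdges <- function(net, v) which(net@from == v)
.inEdges <- function(net, v) which(net@to == v)

# map a node sequence to the edge indices it traverses; errors when a
# consecutive pair is not an edge, or when the pair is ambiguous (parallel
# edges) -- node sequences are only a complete description on simple graphs
.edgesFromNodes <- function(net, nodes) {
  if (length(nodes) < 2L) stop("a path needs at least 2 nodes (one edge)")
  if (anyDuplicated(nodes)) stop("paths do not repeat nodes")
  vapply(seq_len(length(nodes) - 1L), function(i) {
    e <- which(net@from == nodes[i] & net@to == nodes[i + 1L])
    if (length(e) == 0L) {
      stop(sprintf("(%d,%d) is not an edge of the network",
                   nodes[i], nodes[i + 1L]))
    }
    if (length(e) > 1L) {
      stop(sprintf("(%d,%d) is ambiguous: parallel edges", nodes[i],
                   nodes[i + 1L]))
    }
    e
  }, integer(1))
}

.nodesFromEdges <- function(net, edges) {
  c(net@from[edges[1L]], net@to[edges])
}

# resolve either representation into a list(nodes=, edges=)
.asPath <- function(net, path) {
  if (is.list(path) && !is.null(path$edges)) {
    edges <- as.integer(path$edges)
    if (length(edges) > 1L &&
        any(net@to[edges[-length(edges)]] != net@from[edges[-1L]])) {
      stop("edge sequence is not a path")
    }
    list(nodes = .nodesFromEdges(net, edges), edges = edges)
  } else {
    nodes <- as.integer(if (is.list(path)) path$nodes else path)
    list(nodes = nodes, edges = .edgesFromNodes(net, nodes))
  }
}

# is `a` a contiguous subsequence of `b`? (node sequences)
.isSubpath <- function(a, b) {
  la <- length(a); lb <- length(b)
  if (la > lb) return(FALSE)
  for (i in seq_len(lb - la + 1L)) {
    if (all(b[i:(i + la - 1L)] == a)) return(TRUE)
  }
  FALSE
}

.pathKey <- function(p) paste(p, collapse = ",")

# deterministic lexicographic order of integer-vector paths
.orderPaths <- function(paths) {
  if (!length(paths)) return(integer(0))
  keys <- vapply(paths, function(p) {
    paste(sprintf("%012d", p), collapse = "/")
  }, character(1))
  order(keys)
}

#' Canonicalize a set of reported paths
#'
#' Post-processing applied to every safety report: removes duplicate node
#' sequences and any path that is a contiguous subpath of another reported
#' path (in particular prefixes and suffixes), and sorts the survivors
#' lexicographically by node sequence. The result is an antichain under the
#' contiguous-subpath relation.
#'
#' @param paths List of integer vectors (node sequences).
#' @return List of integer vectors, deduplicated, maximal, sorted.
#' @examples
#' canonicalizePaths(list(c(0L, 1L), c(0L, 1L, 3L), c(1L, 3L)))
#' @export
canonicalizePaths <- function(paths) {
  if (!length(paths)) return(list())
  paths <- lapply(paths, as.integer)
  paths <- paths[!duplicated(vapply(paths, .pathKey, character(1)))]
  keep <- vapply(seq_along(paths), function(i) {
    !any(vapply(seq_along(paths), function(j) {
      j != i && .isSubpath(paths[[i]], paths[[j]])
    }, logical(1)))
  }, logical(1))
  paths <- paths[keep]
  paths[.orderPaths(paths)]
}
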