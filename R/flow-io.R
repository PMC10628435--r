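#' Read and write flow-graph files
#'
#' Reads files in the plain-text dialect used by the community flow-graph
#' benchmark collections: one or more blocks, each consisting of a comment
#' line starting with `#` (the graph label), a line with the node count n,
#' then one line `u v f` per edge with integer node identifiers in `[0, n)`
#' and integer flow `f >= 1`. The source and sink of each graph are inferred
#' from the degrees.
#'
#' @param path Path to the file (or a character vector of lines via
#'   `text = TRUE` semantics is not supported; use a temporary file).
#' @param augment Logical: when a block has several sources or sinks, add a
#'   super-source/super-sink (node ids `-1` and `n`) with edges carrying each
#'   original endpoint's flow imbalance instead of raising an error.
#' @return For `readGraphFile`, a list of [FlowNetwork] objects in file order.
#' @examples
#' f <- tempfile(fileext = ".graph")
#' writeGraphFile(list(instanceNetwork(gadget("path"))), f)
#' readGraphFile(f)
#' @export
readGraphFile <- function(path, augment = FALSE) {
  lines <- readLines(path)
  nets <- list()
  i <- 1L
  n_lines <- length(lines)
  while (i <= n_lines) {
    line <- trimws(lines[i])
    if (line == "") { i <- i + 1L; next }
    if (!startsWith(line, "#")) {
      stop(sprintf("line %d: expected '#'-comment graph header, got '%s'",
                   i, line))
    }
    label <- trimws(sub("^#", "", line))
    i <- i + 1L
    if (i > n_lines) stop(sprintf("line %d: missing node-count line", i))
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 2L) {
      stop(sprintf("line %d: invalid node count '%s'", i, lines[i]))
    }
    i <- i + 1L
    from <- integer(); to <- integer(); flow <- numeric()
    while (i <= n_lines && !startsWith(trimws(lines[i]), "#")) {
      line <- trimws(lines[i])
      if (line != "") {
        parts <- strsplit(line, "[[:space:]]+")[[1]]
        vals <- suppressWarnings(as.numeric(parts))
        if (length(vals) != 3L || anyNA(vals) || any(vals != round(vals))) {
          stop(sprintf("line %d: malformed edge line '%s'", i, line))
        }
        if (vals[1] < 0 || vals[1] >= n || vals[2] < 0 || vals[2] >= n) {
          stop(sprintf("line %d: node id outside [0,%d)", i, n))
        }
        if (vals[3] <= 0) {
          stop(sprintf("line %d: edge flow must be positive, got %g",
                       i, vals[3]))
        }
        from <- c(from, as.integer(vals[1]))
        to <- c(to, as.integer(vals[2]))
        flow <- c(flow, vals[3])
      }
      i <- i + 1L
    }
    if (!length(from)) stop(sprintf("graph '%s' has no edges", label))
    nodes <- sort(unique(c(from, to)))
    sources <- setdiff(nodes, to)
    sinks <- setdiff(nodes, from)
    if ((length(sources) != 1L || length(sinks) != 1L)) {
      if (!augment) {
        stop(sprintf(
          "graph '%s' has %d sources and %d sinks; set augment=TRUE",
          label, length(sources), length(sinks)))
      }
      imbalance <- vapply(nodes, function(v) {
        sum(flow[to == v]) - sum(flow[from == v])
      }, numeric(1))
      names(imbalance) <- nodes
      if (length(sources) > 1L) {
        for (v in sources) {
          from <- c(from, -1L); to <- c(to, v)
          flow <- c(flow, -imbalance[[as.character(v)]])
        }
      }
      if (length(sinks) > 1L) {
        for (v in sinks) {
          from <- c(from, v); to <- c(to, n)
          flow <- c(flow, imbalance[[as.character(v)]])
        }
      }
    }
    nets[[length(nets) + 1L]] <-
      flowNetwork(from, to, flow, graphId = label)
  }
  nets
}

#' @rdname readGraphFile
#' @param networks List of [FlowNetwork] objects.
#' @export
writeGraphFile <- function(networks, path) {
  lines <- character()
  for (net in networks) {
    n <- max(net@nodes) + 1L
    lines <- c(lines,
               paste("#", net@graphId),
               as.character(n),
               sprintf("%d %d %g", net@from, net@to, net@flow))
  }
  writeLines(lines, path)
  invisible(NULL)
}

#' Read and write ground-truth and reported-path files
#'
#' Truth and decomposition files carry, per graph, a header line
#' `# graph <id>` followed by one line per path: `weight<TAB>node ids`
#' (space-separated). Safety output and constraint files use the same header
#' and one line of space-separated node ids per path.
#'
#' @param path File path.
#' @return `readTruthFile` returns a named list (graph id ->
#'   `list(paths = list, weights = integer)`); `readPathFile` a named list
#'   (graph id -> list of integer node vectors).
#' @export
readTruthFile <- function(path) {
  lines <- readLines(path)
  out <- list()
  cur <- NULL
  for (line in lines) {
    line <- trimws(line)
    if (line == "") next
    if (startsWith(line, "#")) {
      cur <- trimws(sub("^#\\s*graph\\s*", "", line))
      out[[cur]] <- list(paths = list(), weights = integer())
    } else {
      if (is.null(cur)) stop("path line before any '# graph' header")
      parts <- strsplit(line, "[[:space:]]+")[[1]]
      w <- as.integer(parts[1])
      p <- as.integer(parts[-1])
      out[[cur]]$paths <- c(out[[cur]]$paths, list(p))
      out[[cur]]$weights <- c(out[[cur]]$weights, w)
    }
  }
  out
}

#' @rdname readTruthFile
#' @export
readPathFile <- function(path) {
  lines <- readLines(path)
  out <- list()
  cur <- NULL
  for (line in lines) {
    line <- trimws(line)
    if (line == "") next
    if (startsWith(line, "#")) {
      cur <- trimws(sub("^#\\s*graph\\s*", "", line))
      cur <- sub("\\s+mode=.*$", "", cur)
      out[[cur]] <- list()
    } else {
      if (is.null(cur)) stop("path line before any '# graph' header")
      out[[cur]] <- c(out[[cur]],
                      list(as.integer(strsplit(line, "[[:space:]]+")[[1]])))
    }
  }
  out
}
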