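test_that("graph files round-trip through the plain-text dialect", {
  f <- tempfile(fileext = ".graph")
  writeLines(c("# g0", "3", "0 1 5", "1 2 5"), f)
  nets <- readGraphFile(f)
  expect_length(nets, 1L)
  net <- nets[[1]]
  expect_identical(sourceNode(net), 0L)
  expect_identical(sinkNode(net), 2L)
  expect_identical(numNodes(net), 3L)
  expect_equal(edgeTable(net)$flow, c(5, 5))

  # multi-graph file: crossing gadget plus the path gadget, field-by-field
  nets <- list(instanceNetwork(gadget("crossing")),
               instanceNetwork(gadget("path")))
  writeGraphFile(nets, f)
  back <- readGraphFile(f)
  expect_length(back, 2L)
  for (i in 1:2) {
    expect_identical(edgeTable(back[[i]]), edgeTable(nets[[i]]))
    expect_identical(graphId(back[[i]]), graphId(nets[[i]]))
    expect_identical(sourceNode(back[[i]]), sourceNode(nets[[i]]))
    expect_identical(sinkNode(back[[i]]), sinkNode(nets[[i]]))
  }

  # empty list -> empty file -> empty list
  writeGraphFile(list(), f)
  expect_length(readGraphFile(f), 0L)
})

test_that("random generated instances round-trip exactly", {
  f <- tempfile(fileext = ".graph")
  insts <- lapply(1:50, function(s) {
    generateInstance(sample(4:9, 1), sample(1:3, 1), seed = s,
                     requireNontrivial = FALSE)
  })
  nets <- lapply(insts, instanceNetwork)
  writeGraphFile(nets, f)
  back <- readGraphFile(f)
  expect_length(back, 50L)
  for (i in seq_along(nets)) {
    expect_identical(edgeTable(back[[i]]), edgeTable(nets[[i]]))
  }
})

test_that("parser rejects malformed input with line numbers", {
  f <- tempfile()
  writeLines(c("# g", "3", "0 1 0"), f)
  expect_error(readGraphFile(f), "flow must be positive")
  writeLines(c("# g", "3", "0 one 5"), f)
  expect_error(readGraphFile(f), "line 3")
  writeLines(c("3", "0 1 5"), f)
  expect_error(readGraphFile(f), "header")
  writeLines(c("# g", "3", "0 5 1"), f)
  expect_error(readGraphFile(f), "outside")
})

test_that("multiple sources/sinks are rejected unless augmentation is on", {
  f <- tempfile()
  # two sources 0 and 1, one sink 3
  writeLines(c("# g", "4", "0 2 1", "1 2 2", "2 3 3"), f)
  expect_error(readGraphFile(f), "2 sources")
  aug <- readGraphFile(f, augment = TRUE)[[1]]
  expect_length(flowViolations(aug), 0L)
  et <- edgeTable(aug)
  expect_equal(et$flow[et$from == -1L & et$to == 0L], 1)
  expect_equal(et$flow[et$from == -1L & et$to == 1L], 2)
})

test_that("flowViolations pinpoints broken invariants", {
  good <- flowNetwork(c(0L, 1L), c(1L, 2L), c(5, 5))
  expect_length(flowViolations(good), 0L)

  lost <- flowNetwork(c(0L, 1L), c(1L, 2L), c(5, 4))
  v <- flowViolations(lost)
  expect_length(v, 1L)
  expect_match(v, "conservation .* node 1", all = FALSE)

  cyc <- flowNetwork(c(0L, 1L, 2L, 1L), c(1L, 2L, 3L, 1L), c(2, 2, 2, 2),
                     source = 0L, sink = 3L)
  expect_match(flowViolations(cyc), "acyclic", all = FALSE)
})

test_that("excess flow matches the hand computation on g4", {
  g4 <- instanceNetwork(gadget("g4"))
  # single edge: its own flow, no internal nodes
  expect_equal(excessFlow(g4, c(0L, 2L)), 2)
  # first-edge flow 1 minus node b's off-path out-flow 2
  expect_equal(excessFlow(g4, c(0L, 1L, 2L, 4L)), -1)
  expect_equal(excessFlow(g4, c(0L, 1L, 2L)), 1)
  expect_equal(excessFlow(g4, c(0L, 2L, 3L, 5L)), 1)
  expect_false(isSafeAllFDs(g4, c(0L, 1L, 2L, 4L)))
  expect_true(isSafeAllFDs(g4, c(0L, 2L, 3L, 5L)))
  expect_error(excessFlow(g4, c(0L, 3L)), "not an edge")
})

test_that("Y-to-V contraction produces the extended unitigs", {
  # path graph contracts to a single source-sink edge
  pg <- flowNetwork(c(0L, 1L, 2L), c(1L, 2L, 3L), c(5, 5, 5))
  cm <- contractYtoV(pg)
  expect_identical(numEdges(contractedNetwork(cm)), 1L)
  expect_identical(contractedEdgePaths(cm)[[1]], c(0L, 1L, 2L, 3L))

  # crossing gadget: two parallel edge pairs around the hub
  cm <- contractYtoV(instanceNetwork(gadget("crossing")))
  cnet <- contractedNetwork(cm)
  expect_identical(numEdges(cnet), 4L)
  expect_same_path_set(contractedEdgePaths(cm),
                       list(c(0L, 1L, 3L), c(0L, 2L, 3L),
                            c(3L, 4L, 6L), c(3L, 5L, 6L)))
  # expansion reproduces the original flow edge by edge
  g <- instanceNetwork(gadget("crossing"))
  et <- edgeTable(g)
  f <- numeric(nrow(et))
  cet <- edgeTable(cnet)
  for (e in seq_along(contractedEdgePaths(cm))) {
    p <- contractedEdgePaths(cm)[[e]]
    for (j in seq_len(length(p) - 1L)) {
      idx <- which(et$from == p[j] & et$to == p[j + 1L])
      f[idx] <- f[idx] + cet$flow[e]
    }
  }
  expect_equal(f, et$flow)

  # an already-stable multigraph is returned unchanged
  stable <- flowNetwork(c(0L, 0L, 3L, 3L), c(3L, 3L, 6L, 6L), rep(2, 4))
  cm <- contractYtoV(stable)
  expect_identical(edgeTable(contractedNetwork(cm)), edgeTable(stable))
  expect_true(all(lengths(contractedEdgePaths(cm)) == 2L))
})

test_that("every contracted edge is a genuine safe extended unitig", {
  # interior must be in-degree-one nodes then out-degree-one nodes, which is
  # equivalent to being safe for every flow decomposition (positive excess)
  for (s in 1:30) {
    inst <- generateInstance(sample(5:9, 1), sample(2:3, 1), seed = s,
                             requireNontrivial = FALSE)
    net <- instanceNetwork(inst)
    cm <- contractYtoV(net)
    et <- edgeTable(net)
    for (p in contractedEdgePaths(cm)) {
      expect_true(isSafeAllFDs(net, p),
                  info = paste("seed", s, paste(p, collapse = " ")))
      interior <- p[-c(1, length(p))]
      indeg1 <- vapply(interior, function(v) sum(et$to == v) == 1L,
                       logical(1))
      outdeg1 <- vapply(interior, function(v) sum(et$from == v) == 1L,
                        logical(1))
      expect_true(all(indeg1 | outdeg1))
      # in-degree-one block strictly precedes the out-degree-one block
      boundary <- which(!indeg1)
      if (length(boundary)) {
        expect_true(all(outdeg1[boundary[1]:length(interior)]))
      }
    }
  }
})

test_that("expanded contracted paths are valid original paths", {
  # DFS over the contracted multigraph by edge indices
  stPathsEdges <- function(net) {
    et <- edgeTable(net)
    out <- list()
    recurse <- function(v, edges) {
      if (v == sinkNode(net)) {
        out[[length(out) + 1L]] <<- edges
        return(invisible())
      }
      for (e in which(et$from == v)) recurse(et$to[e], c(edges, e))
    }
    recurse(sourceNode(net), integer(0))
    out
  }
  for (s in 1:20) {
    inst <- generateInstance(sample(5:8, 1), sample(2:3, 1), seed = s,
                             requireNontrivial = FALSE)
    net <- instanceNetwork(inst)
    cm <- contractYtoV(net)
    et <- edgeTable(net)
    for (ep in stPathsEdges(contractedNetwork(cm))) {
      full <- expandPath(cm, list(edges = ep))
      expect_identical(full[1], sourceNode(net))
      expect_identical(full[length(full)], sinkNode(net))
      for (j in seq_len(length(full) - 1L)) {
        expect_true(any(et$from == full[j] & et$to == full[j + 1L]))
      }
      expect_false(anyDuplicated(full) > 0)
    }
  }
})

test_that("funnel detection matches the unique-decomposition property", {
  expect_true(isFunnel(instanceNetwork(gadget("path"))))
  expect_false(isFunnel(instanceNetwork(gadget("crossing"))))
  # g4 has a unique MFD but several FDs and is not a funnel
  expect_false(isFunnel(instanceNetwork(gadget("g4"))))
  # oracle agreement: a funnel is a graph whose decomposition is unique up
  # to splitting weights, i.e. every FD uses the same set of distinct paths
  for (s in 1:25) {
    inst <- generateInstance(5, 2, seed = s, requireNontrivial = FALSE,
                             weightSampler = function(n) rep(2L, n))
    net <- instanceNetwork(inst)
    if (sourceOutflow(net) > 8 || numEdges(net) > 14) next
    pathSets <- unique(vapply(enumerateAllFDs(net), function(d) {
      paste(sortedKeys(unique(decompositionPaths(d))), collapse = " | ")
    }, character(1)))
    expect_identical(isFunnel(net), length(pathSets) == 1L,
                     info = paste("seed", s))
  }
})

test_that("greedy decomposition superposes exactly to the flow", {
  for (nm in c("path", "crossing", "g4", "three_path")) {
    net <- instanceNetwork(gadget(nm))
    fd <- greedyFlowDecomposition(net)
    expect_equal(superposeByHand(net, decompositionPaths(fd), pathWeights(fd)),
                 edgeTable(net)$flow, info = nm)
    expect_true(all(pathWeights(fd) >= 1))
  }
  net <- instanceNetwork(gadget("crossing"))
  fd <- greedyFlowDecomposition(net)
  expect_length(decompositionPaths(fd), 2L)
  expect_equal(pathWeights(fd), c(2L, 2L))
  for (s in 1:20) {
    inst <- generateInstance(sample(5:9, 1), sample(2:4, 1), seed = s,
                             requireNontrivial = FALSE)
    net <- instanceNetwork(inst)
    fd <- greedyFlowDecomposition(net)
    expect_equal(superposeByHand(net, decompositionPaths(fd), pathWeights(fd)),
                 edgeTable(net)$flow, info = paste("seed", s))
  }
})

test_that("canonicalization removes duplicates, prefixes and suffixes", {
  expect_identical(canonicalizePaths(list(c(0L, 1L, 3L), c(0L, 1L, 3L))),
                   list(c(0L, 1L, 3L)))
  expect_identical(canonicalizePaths(list(c(0L, 1L), c(0L, 1L, 3L))),
                   list(c(0L, 1L, 3L)))
  expect_identical(canonicalizePaths(list(c(1L, 3L), c(0L, 1L, 3L))),
                   list(c(0L, 1L, 3L)))
  # non-contiguous subsequences are NOT removed
  expect_length(canonicalizePaths(list(c(0L, 2L), c(0L, 1L, 2L))), 2L)
  # deterministic lexicographic order
  out <- canonicalizePaths(list(c(3L, 4L), c(0L, 5L), c(0L, 1L)))
  expect_identical(out, list(c(0L, 1L), c(0L, 5L), c(3L, 4L)))
})
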