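test_that("an unavoidable tested path forces its indicator to zero", {
  # 6-node path s,a,b,c,d,e: the single solution path uses all five edges,
  # so the avoidance constraint reads x_sa+x_ab+x_bc+x_cd+x_de <= 5 - gamma
  # with every indicator at 1, forcing gamma = 0 at the maximum
  net <- flowNetwork(0:4, 1:5, rep(7, 5))
  gt <- groupTest(net, 1, list(0:5))
  expect_identical(gt$status, "optimal")
  expect_identical(gt$objective, 0)
  expect_identical(gt$statusMap, "safe")
  expect_length(gt$N, 0L)
})

test_that("group test on the crossing gadget matches hand enumeration", {
  net <- instanceNetwork(gadget("crossing"))
  # both arms appear in both minimum decompositions -> nothing avoidable
  gt <- groupTest(net, 2, list(c(0L, 1L, 3L), c(3L, 4L, 6L)))
  expect_identical(gt$objective, 0)
  expect_identical(gt$statusMap, c("safe", "safe"))

  # (s,a,c,d) is avoided by the other minimum decomposition
  gt <- groupTest(net, 2, list(c(0L, 1L, 3L, 4L)))
  expect_identical(gt$objective, 1)
  expect_length(gt$N, 1L)
  expect_identical(gt$N[[1]]$nodes, c(0L, 1L, 3L, 4L))

  # (s,a,c) is unavoidable, (a,c,d) is not: optimum is exactly 1
  gt <- groupTest(net, 2, list(c(0L, 1L, 3L), c(1L, 3L, 4L)))
  expect_identical(gt$objective, 1)
  expect_identical(gt$statusMap, c("unknown", "unsafe"))

  # both full paths of one decomposition avoided simultaneously by the other
  gt <- groupTest(net, 2, list(c(0L, 1L, 3L, 4L, 6L), c(0L, 2L, 3L, 5L, 6L)))
  expect_identical(gt$objective, 2)
})

test_that("avoidance objective equals the brute-force maximum", {
  suite <- makeOracleSuite(12)
  for (inst in suite) {
    net <- instanceNetwork(inst)
    fit <- findMinimumK(net)
    decs <- enumerateAllFDs(net, fit$k)
    # tested set: all windows of the first minimum decomposition's paths
    tested <- list()
    for (p in decompositionPaths(decs[[1]])) {
      tested <- c(tested, allWindows(p))
    }
    tested <- tested[!duplicated(vapply(tested, pathKey, character(1)))]
    gt <- groupTest(net, fit$k, tested)
    bfBest <- max(vapply(decs, function(d) {
      sum(vapply(tested, function(w) {
        !any(vapply(decompositionPaths(d), function(p) isSubseq(w, p),
                    logical(1)))
      }, logical(1)))
    }, numeric(1)))
    expect_identical(gt$objective, bfBest, info = graphId(net))
    # every avoided path is really absent from some minimum decomposition
    for (p in gt$N) {
      expect_true(any(vapply(decs, function(d) {
        !any(vapply(decompositionPaths(d), function(q) isSubseq(p$nodes, q),
                    logical(1)))
      }, logical(1))))
    }
  }
})

test_that("the recursive resolution partitions paths in few calls", {
  net <- instanceNetwork(gadget("crossing"))
  gs <- getSafe(net, 2, list(c(0L, 1L, 3L), c(0L, 1L, 3L, 4L), c(3L, 4L, 6L)))
  expect_same_path_set(lapply(gs$safe, `[[`, "nodes"),
                       list(c(0L, 1L, 3L), c(3L, 4L, 6L)))
  expect_same_path_set(lapply(gs$unsafe, `[[`, "nodes"),
                       list(c(0L, 1L, 3L, 4L)))
  expect_identical(gs$calls, 2L)

  # singleton: one call decides the path
  gs <- getSafe(net, 2, list(c(0L, 1L, 3L)))
  expect_identical(gs$calls, 1L)
  expect_length(gs$safe, 1L)

  # empty input: no calls
  gs <- getSafe(net, 2, list())
  expect_identical(gs$calls, 0L)
  expect_length(gs$safe, 0L)
  expect_length(gs$unsafe, 0L)

  # call-count bound: at most u + 1 calls for u unsafe paths, exactly 1
  # when everything is safe
  suite <- makeOracleSuite(10)
  for (inst in suite) {
    net <- instanceNetwork(inst)
    fit <- findMinimumK(net)
    tested <- list()
    for (p in decompositionPaths(fit$decomposition)) {
      tested <- c(tested, allWindows(p))
    }
    tested <- tested[!duplicated(vapply(tested, pathKey, character(1)))]
    gs <- getSafe(net, fit$k, tested)
    expect_lte(gs$calls, length(gs$unsafe) + 1L)
    if (length(gs$unsafe) == 0L) expect_identical(gs$calls, 1L)
  }
})

test_that("duplicate tested paths are merged with a warning", {
  net <- instanceNetwork(gadget("crossing"))
  model <- buildFdModel(net, 2)
  expect_warning(m2 <- addSafetyLayer(model, list(c(0L, 1L, 3L), c(0L, 1L, 3L))),
                 "duplicate")
  expect_length(m2$testedPaths, 1L)
  expect_error(addSafetyLayer(model, list(c(0L, 6L))), "not an edge")
})

test_that("excess-flow prefilter splits by the characterization", {
  g4 <- instanceNetwork(gadget("g4"))
  pre <- excessFlowPrefilter(g4, list(c(0L, 1L, 2L), c(0L, 1L, 2L, 4L)))
  expect_identical(lapply(pre$flowSafe, `[[`, "nodes"),
                   list(c(0L, 1L, 2L)))
  expect_identical(lapply(pre$toTest, `[[`, "nodes"),
                   list(c(0L, 1L, 2L, 4L)))
  pre <- excessFlowPrefilter(g4, list())
  expect_length(pre$flowSafe, 0L)
  expect_length(pre$toTest, 0L)
  # single-edge paths always pass (positive flow, no internal nodes)
  et <- edgeTable(g4)
  singles <- lapply(seq_len(nrow(et)), function(e) c(et$from[e], et$to[e]))
  pre <- excessFlowPrefilter(g4, singles)
  expect_length(pre$toTest, 0L)
})

test_that("flow-safe paths are always a subset of minimum-decomposition safe", {
  suite <- makeOracleSuite(10)
  for (inst in suite) {
    net <- instanceNetwork(inst)
    mfdSafe <- bruteForceSafe(net, "mfd")
    allSafe <- bruteForceSafe(net, "all_fd")
    for (p in allSafe) {
      expect_true(any(vapply(mfdSafe, function(q) isSubseq(p, q),
                             logical(1))),
                  info = graphId(net))
    }
  }
})
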