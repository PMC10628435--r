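test_that("gadget safe sets match the oracle-derived fixtures", {
  # crossing: only the four arms around the hub are safe
  rep <- findAllMaximalSafeMFD(instanceNetwork(gadget("crossing")))
  expect_identical(reportMode(rep), "mfd_safe")
  expect_same_path_set(safePaths(rep),
                       list(c(0L, 1L, 3L), c(0L, 2L, 3L),
                            c(3L, 4L, 6L), c(3L, 5L, 6L)))

  # g4: the unique minimum decomposition makes both full paths safe,
  # strictly longer than the safe-for-all-FDs set
  g4 <- instanceNetwork(gadget("g4"))
  rep <- findAllMaximalSafeMFD(g4)
  expect_same_path_set(safePaths(rep),
                       list(c(0L, 1L, 2L, 4L, 5L), c(0L, 2L, 3L, 5L)))
  allFd <- safePathsAllFDs(g4)
  expect_identical(reportMode(allFd), "all_fd")
  expect_same_path_set(safePaths(allFd),
                       list(c(0L, 1L, 2L), c(2L, 4L, 5L), c(0L, 2L, 3L, 5L)))
  # every all-FD-safe path extends to a minimum-decomposition-safe path
  for (p in safePaths(allFd)) {
    expect_true(any(vapply(safePaths(rep), function(q) isSubseq(p, q),
                           logical(1))))
  }

  # funnel: full path reported without any solver call
  rep <- findAllMaximalSafeMFD(instanceNetwork(gadget("path")))
  expect_identical(safePaths(rep), list(c(0L, 1L, 2L)))
  expect_identical(ilpCalls(rep), 0L)
  expect_identical(rep@provenance, "funnel")
})

test_that("trimming on a funnel core reports everything in round one", {
  pg <- instanceNetwork(gadget("path"))
  fit <- findMinimumK(pg)
  rep <- trimMaximalSafe(instanceNetwork(gadget("path")), fit$k,
                         fit$decomposition)
  expect_identical(safePaths(rep), list(c(0L, 1L, 2L)))
  # the full path has positive excess flow, so even the trim run needs no ILP
  expect_identical(ilpCalls(rep), 0L)
})

test_that("outer algorithms agree and trimming needs no more ILP calls", {
  suite <- makeOracleSuite(25)
  trimTotal <- 0L
  tpTotal <- 0L
  for (inst in suite) {
    net <- instanceNetwork(inst)
    fit <- findMinimumK(net)
    a <- trimMaximalSafe(net, fit$k, fit$decomposition)
    b <- twoPointerMaximalSafe(net, fit$k, fit$decomposition)
    expect_same_path_set(safePaths(a), safePaths(b))
    trimTotal <- trimTotal + ilpCalls(a)
    tpTotal <- tpTotal + ilpCalls(b)
  }
  expect_lte(trimTotal, tpTotal)
})

test_that("safe-for-all-FDs scan equals its brute-force enumeration", {
  suite <- makeOracleSuite(15)
  for (inst in suite) {
    net <- instanceNetwork(inst)
    expect_same_path_set(safePaths(safePathsAllFDs(net)),
                         bruteForceSafe(net, "all_fd"))
  }
})

test_that("extended unitigs are the contracted edges, canonicalized", {
  rep <- extendedUnitigs(instanceNetwork(gadget("path")))
  expect_identical(safePaths(rep), list(c(0L, 1L, 2L)))
  rep <- extendedUnitigs(instanceNetwork(gadget("crossing")))
  expect_same_path_set(safePaths(rep),
                       list(c(0L, 1L, 3L), c(0L, 2L, 3L),
                            c(3L, 4L, 6L), c(3L, 5L, 6L)))
  # g4 keeps the single-edge unitig (s,b): it is not a contiguous subpath
  # of any longer unitig
  rep <- extendedUnitigs(instanceNetwork(gadget("g4")))
  expect_same_path_set(safePaths(rep),
                       list(c(0L, 1L, 2L), c(0L, 2L), c(2L, 3L, 5L),
                            c(2L, 4L, 5L)))
})

test_that("unitigs nest inside all-FD-safe inside minimum-safe paths", {
  suite <- makeOracleSuite(15)
  for (inst in suite) {
    net <- instanceNetwork(inst)
    eu <- safePaths(extendedUnitigs(net))
    af <- safePaths(safePathsAllFDs(net))
    mf <- safePaths(findAllMaximalSafeMFD(net))
    for (p in eu) {
      expect_true(any(vapply(af, function(q) isSubseq(p, q), logical(1))),
                  info = paste(graphId(net), "eunitig"))
    }
    for (p in af) {
      expect_true(any(vapply(mf, function(q) isSubseq(p, q), logical(1))),
                  info = paste(graphId(net), "all-fd"))
    }
  }
})

test_that("a zero time budget falls back to the all-FD baseline", {
  net <- instanceNetwork(gadget("crossing"))
  rep <- findAllMaximalSafeMFD(net, timeBudget = 0)
  expect_identical(reportMode(rep), "all_fd_fallback")
  expect_true(rep@timedOut)
  expect_true(all(rep@provenance == "fallback_all_fd"))
  expect_same_path_set(safePaths(rep), safePaths(safePathsAllFDs(net)))
})

test_that("reports are canonical: no duplicates, no nested paths", {
  suite <- makeOracleSuite(10)
  for (inst in suite) {
    rep <- findAllMaximalSafeMFD(instanceNetwork(inst))
    ps <- safePaths(rep)
    expect_false(any(duplicated(vapply(ps, pathKey, character(1)))))
    for (i in seq_along(ps)) {
      for (j in seq_along(ps)) {
        if (i != j) expect_false(isSubseq(ps[[i]], ps[[j]]))
      }
    }
    # deterministic lexicographic order
    expect_identical(vapply(ps, pathKey, character(1)),
                     vapply(canonicalizePaths(ps), pathKey, character(1)))
  }
})

test_that("reported paths are maximal: one-node extensions are unsafe", {
  suite <- makeOracleSuite(8)
  for (inst in suite) {
    net <- instanceNetwork(inst)
    oracle <- bruteForceSafe(net, "mfd")
    et <- edgeTable(net)
    for (p in safePaths(findAllMaximalSafeMFD(net))) {
      # the path itself must be one of the oracle's maximal safe paths
      expect_true(pathKey(p) %in% vapply(oracle, pathKey, character(1)),
                  info = graphId(net))
      left <- et$from[et$to == p[1]]
      for (u in left) {
        expect_false(any(vapply(oracle, function(q) {
          isSubseq(c(u, p), q)
        }, logical(1))), info = graphId(net))
      }
      right <- et$to[et$from == p[length(p)]]
      for (w in right) {
        expect_false(any(vapply(oracle, function(q) {
          isSubseq(c(p, w), q)
        }, logical(1))), info = graphId(net))
      }
    }
  }
})
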