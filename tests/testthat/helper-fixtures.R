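# shared fixtures and comparison helpers

pathKey <- function(p) paste(p, collapse = ",")
sortedKeys <- function(paths) sort(vapply(paths, pathKey, character(1)))
expect_same_path_set <- function(a, b) {
  expect_identical(sortedKeys(a), sortedKeys(b))
}

isSubseq <- function(a, b) {
  la <- length(a); lb <- length(b)
  if (la > lb) return(FALSE)
  any(vapply(seq_len(lb - la + 1L), function(i) {
    all(b[i:(i + la - 1L)] == a)
  }, logical(1)))
}

sourceOutflow <- function(net) {
  et <- edgeTable(net)
  sum(et$flow[et$from == sourceNode(net)])
}

# superposition of weighted node paths recomputed independently of the
# package internals (simple graphs only)
superposeByHand <- function(net, paths, weights) {
  et <- edgeTable(net)
  f <- numeric(nrow(et))
  for (i in seq_along(paths)) {
    p <- paths[[i]]
    for (j in seq_len(length(p) - 1L)) {
      e <- which(et$from == p[j] & et$to == p[j + 1L])
      f[e] <- f[e] + weights[i]
    }
  }
  f
}

# deterministic oracle-scale benchmark instances: <= 8 nodes, unit-ish
# weights so the total source out-flow stays <= 8, funnels excluded
makeOracleInstance <- function(seed) {
  nNodes <- 5L + (seed %% 4L)
  t <- 2L + (seed %% 2L)
  inst <- tryCatch(
    generateInstance(nNodes, t,
                     weightSampler = function(n) sample.int(3L, n, TRUE),
                     seed = seed),
    error = function(e) NULL)
  if (is.null(inst)) return(NULL)
  net <- instanceNetwork(inst)
  if (sourceOutflow(net) > 8 || numEdges(net) > 14) return(NULL)
  inst
}

makeOracleSuite <- function(n, seedStart = 1L) {
  out <- list()
  seed <- seedStart
  while (length(out) < n && seed < seedStart + 50L * n) {
    inst <- makeOracleInstance(seed)
    if (!is.null(inst)) out[[length(out) + 1L]] <- inst
    seed <- seed + 1L
  }
  out
}

# all contiguous windows (>= 1 edge) of a node path
allWindows <- function(p) {
  out <- list()
  L <- length(p)
  for (a in seq_len(L - 1L)) {
    for (b in (a + 1L):L) out <- c(out, list(p[a:b]))
  }
  out
}
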