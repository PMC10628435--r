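# Transcript-recovery quality metrics: reported safe paths are compared
# against ground-truth transcript paths per graph, with exact node (exon)
# alignment, and averaged over graphs.

#' Is a reported path correct?
#'
#' A reported path is correct iff it is a contiguous node subsequence of some
#' ground-truth transcript path (exact alignment of exons/nodes).
#'
#' @param reported Integer node sequence.
#' @param truth List of integer node sequences (ground-truth paths).
#' @return Logical scalar.
#' @export
isCorrectPath <- function(reported, truth) {
  any(vapply(truth, function(p) .isSubpath(reported, p), logical(1)))
}

#' Weighted precision of a set of reported paths
#'
#' Total length (in nodes) of the correctly reported paths divided by the
#' total length of all reported paths. An empty reported set has no incorrect
#' length and scores 1 by convention, with a warning, since the benchmark
#' definition leaves this corner open. `method = "mean"` instead averages the
#' per-path 0/1 correctness weighted by nothing (the alternative per-graph
#' aggregation phrasing); the length-ratio is the default.
#'
#' @param reported List of integer node sequences (canonicalized).
#' @param truth List of ground-truth node sequences.
#' @param method `"length_ratio"` (default) or `"mean"`.
#' @return Fraction in `[0, 1]`.
#' @export
weightedPrecision <- function(reported, truth,
                              method = c("length_ratio", "mean")) {
  method <- match.arg(method)
  if (!length(reported)) {
    warning("empty reported set: weighted precision is vacuously 1")
    return(1)
  }
  correct <- vapply(reported, isCorrectPath, logical(1), truth = truth)
  len <- lengths(reported)
  if (method == "length_ratio") {
    sum(len[correct]) / sum(len)
  } else {
    mean(correct)
  }
}

#' Maximum coverage of a ground-truth path
#'
#' The length of the longest contiguous segment of the truth path that equals
#' a contiguous segment of some reported path, divided by the truth path
#' length (in nodes); 0 when no reported path shares a segment.
#'
#' @param reported List of integer node sequences.
#' @param truthPath Integer node sequence.
#' @return Fraction in `[0, 1]`.
#' @export
maxCoverage <- function(reported, truthPath) {
  if (!length(reported)) return(0)
  best <- max(vapply(reported, function(r) {
    .longestCommonSegment(truthPath, r)
  }, numeric(1)))
  best / length(truthPath)
}

# longest common contiguous segment of two integer sequences (classic DP)
.longestCommonSegment <- function(a, b) {
  la <- length(a); lb <- length(b)
  best <- 0L
  prev <- integer(lb)
  for (i in seq_len(la)) {
    cur <- integer(lb)
    for (j in seq_len(lb)) {
      if (a[i] == b[j]) {
        cur[j] <- if (j > 1L) prev[j - 1L] + 1L else 1L
        if (cur[j] > best) best <- cur[j]
      }
    }
    prev <- cur
  }
  best
}

#' F-score
#'
#' Harmonic mean of weighted precision and (average) maximum coverage; 0 when
#' both are 0.
#'
#' @param precision,coverage Fractions in `[0, 1]`.
#' @return Fraction in `[0, 1]`.
#' @export
fScore <- function(precision, coverage) {
  if (precision + coverage == 0) return(0)
  2 * precision * coverage / (precision + coverage)
}

#' Evaluate one graph's reported paths against its ground truth
#'
#' Computes the per-graph metrics: weighted precision over the reported
#' paths, maximum coverage averaged over the ground-truth paths, and their
#' harmonic mean.
#'
#' @param reported List of integer node sequences (or a [SafetyReport]).
#' @param truth List of integer node sequences (ground-truth transcripts).
#' @param graphId Character label.
#' @return A one-row `data.frame` with columns `graphId`, `t` (number of
#'   truth paths), `nReported`, `nCorrect`, `wtPrecision`, `maxCoverage`,
#'   `fScore`, `emptyReported`.
#' @examples
#' inst <- gadget("crossing")
#' rep <- findAllMaximalSafeMFD(instanceNetwork(inst))
#' evaluateGraph(safePaths(rep), transcriptPaths(inst))
#' @export
evaluateGraph <- function(reported, truth, graphId = "g") {
  if (is(reported, "SafetyReport")) {
    if (graphId == "g") graphId <- reported@graphId
    reported <- reported@paths
  }
  empty <- length(reported) == 0L
  p <- if (empty) {
    suppressWarnings(weightedPrecision(reported, truth))
  } else {
    weightedPrecision(reported, truth)
  }
  cov <- mean(vapply(truth, function(tp) maxCoverage(reported, tp),
                     numeric(1)))
  nCorrect <- sum(vapply(reported, isCorrectPath, logical(1), truth = truth))
  data.frame(graphId = graphId, t = length(truth),
             nReported = length(reported), nCorrect = nCorrect,
             wtPrecision = p, maxCoverage = cov, fScore = fScore(p, cov),
             emptyReported = empty, stringsAsFactors = FALSE)
}

#' Aggregate per-graph evaluations into strata
#'
#' Unweighted means of the three metrics over graphs, overall (`"All"`) and
#' restricted to graphs whose number of ground-truth paths t is below each
#' threshold (rows `"t<=10"`, `"t<=15"`, ... matching the benchmark tables).
#'
#' @param evaluations A `data.frame` of rows from [evaluateGraph()].
#' @param tThresholds Integer vector of strata thresholds.
#' @return A `data.frame` with columns `stratum`, `nGraphs`, `maxCoverage`,
#'   `wtPrecision`, `fScore`; empty input yields an empty table.
#' @export
aggregateEvaluations <- function(evaluations, tThresholds = c(10, 15)) {
  if (!NROW(evaluations)) {
    return(data.frame(stratum = character(), nGraphs = integer(),
                      maxCoverage = numeric(), wtPrecision = numeric(),
                      fScore = numeric(), stringsAsFactors = FALSE))
  }
  strata <- c(stats::setNames(as.list(tThresholds),
                              sprintf("t<=%d", tThresholds)),
              list(All = Inf))
  rows <- lapply(names(strata), function(nm) {
    sub <- evaluations[evaluations$t <= strata[[nm]], , drop = FALSE]
    data.frame(stratum = nm, nGraphs = nrow(sub),
               maxCoverage = mean(sub$maxCoverage),
               wtPrecision = mean(sub$wtPrecision),
               fScore = mean(sub$fScore), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
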