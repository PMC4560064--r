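#' @importFrom stats cor
NULL

# Signed-link ids: ordered pair (src, tgt) plus sign (0 = cooperative,
# 1 = competitive) mapped to 1..2n^2 (self-pairs never set).
.link_ids <- function(srcIdx, tgtIdx, sign01, n) {
  sign01 * n * n + (srcIdx - 1L) * n + tgtIdx
}

.edge_link_vector <- function(edgeFrame, nodeIds) {
  n <- length(nodeIds)
  v <- logical(2L * n * n)
  if (!nrow(edgeFrame)) return(v)
  src <- match(edgeFrame$source, nodeIds)
  tgt <- match(edgeFrame$target, nodeIds)
  if (anyNA(src) || anyNA(tgt))
    stop("network references nodes outside the candidate OTU set")
  v[.link_ids(src, tgt, as.integer(edgeFrame$sign == "competitive"), n)] <- TRUE
  v
}

#' Signed links implied by a set of triplets
#'
#' Expands triplet rows into their implied directed signed links (the
#' cooperative `m -> t` and competitive `c -| t` link per triplet) and
#' deduplicates. Unlike [buildNetwork()], no conflict policy applies: a
#' pair implied with both signs yields both links. This union semantics is
#' what the benchmark evaluation scores, and it makes the predicted link
#' set grow monotonically as thresholds are relaxed.
#'
#' @param triplets data.frame with columns `m`, `c`, `t`.
#' @return data.frame with columns `source`, `target`, `sign`, one row per
#'   distinct signed link.
#' @export
tripletLinks <- function(triplets) {
  if (!nrow(triplets))
    return(data.frame(source = character(), target = character(),
                      sign = character(), stringsAsFactors = FALSE))
  out <- data.frame(
    source = c(triplets$m, triplets$c),
    target = c(triplets$t, triplets$t),
    sign = rep(c("cooperative", "competitive"), each = nrow(triplets)),
    stringsAsFactors = FALSE)
  out <- unique(out)
  out[order(out$source, out$target, out$sign), , drop = FALSE]
}

#' Confusion counts over the signed-link universe
#'
#' Compares a predicted signed network with the ground truth over the full
#' candidate universe of `2 n (n - 1)` (ordered pair, sign) links for `n`
#' OTUs (180 links for the ten-OTU benchmark): a candidate is a true
#' positive if predicted and true, a false positive if predicted only, a
#' false negative if true only, and a true negative otherwise.
#'
#' @param predicted a [RegulatoryNetwork] or a data.frame of signed links
#'   (`source`, `target`, `sign`).
#' @param truth the ground-truth [RegulatoryNetwork] (or link data.frame).
#' @param nodeIds the candidate OTU set; defaults to the truth network's
#'   nodes. All predicted nodes must belong to it.
#' @return A list with integer components `tp`, `fp`, `tn`, `fn` and
#'   `universe`.
#' @examples
#' tr <- groundTruthNetwork()
#' confusionCounts(tr, tr)  # tp 14, tn 166
#' @export
confusionCounts <- function(predicted, truth, nodeIds = NULL) {
  tEdges <- if (is(truth, "RegulatoryNetwork")) edges(truth) else truth
  pEdges <- if (is(predicted, "RegulatoryNetwork")) edges(predicted) else predicted
  if (is.null(nodeIds))
    nodeIds <- if (is(truth, "RegulatoryNetwork")) nodes(truth) else
      sort(unique(c(tEdges$source, tEdges$target)))
  n <- length(nodeIds)
  tv <- .edge_link_vector(tEdges, nodeIds)
  pv <- .edge_link_vector(pEdges, nodeIds)
  universe <- 2L * n * (n - 1L)
  tp <- sum(pv & tv)
  fp <- sum(pv & !tv)
  fn <- sum(!pv & tv)
  list(tp = tp, fp = fp, tn = universe - tp - fp - fn, fn = fn,
       universe = universe)
}

#' Evaluation measures from confusion counts
#'
#' Computes the four benchmark measures: `tpr = tp / (tp + fn)`,
#' `tnr = tn / (tn + fp)`, the TPR/TNR harmonic mean
#' `f = 2 tpr tnr / (tpr + tnr)` (0 when both rates are 0), and
#' `accuracy = (tp + tn) / (tp + fn + tn + fp)`.
#'
#' @param counts list with `tp`, `fp`, `tn`, `fn` (e.g. from
#'   [confusionCounts()]).
#' @return Named numeric vector with `accuracy`, `tpr`, `tnr`, `f`.
#' @export
networkMetrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  if (tp + fn == 0) stop("networkMetrics: no positive candidates (tp + fn = 0)")
  if (tn + fp == 0) stop("networkMetrics: no negative candidates (tn + fp = 0)")
  tpr <- tp / (tp + fn)
  tnr <- tn / (tn + fp)
  f <- if (tpr + tnr == 0) 0 else 2 * tpr * tnr / (tpr + tnr)
  c(accuracy = (tp + tn) / (tp + fn + tn + fp), tpr = tpr, tnr = tnr, f = f)
}

#' Efficiency of a network's evaluation measures
#'
#' The efficiency of one evaluated network is the largest value `v` such
#' that at least three of its four measures (accuracy, TPR, TNR,
#' F-measure) are `>= v` — i.e. the third-largest of the four.
#'
#' @param metrics numeric vector (or list) containing the four measures.
#' @return The scalar efficiency.
#' @examples
#' efficiencyScore(c(accuracy = 0.9, tpr = 0.8, tnr = 0.7, f = 0.6))  # 0.7
#' @export
efficiencyScore <- function(metrics) {
  v <- unlist(metrics)[c("accuracy", "tpr", "tnr", "f")]
  if (anyNA(v)) stop("efficiencyScore: requires the four named measures")
  unname(sort(v, decreasing = TRUE)[3L])
}

#' Occurrence rate of an efficiency level
#'
#' Percentage of evaluated networks whose efficiency meets a threshold.
#'
#' @param efficiencies numeric vector of per-network efficiencies.
#' @param v efficiency level.
#' @return Percentage in \[0, 100\].
#' @export
occurrenceRate <- function(efficiencies, v) {
  if (!length(efficiencies)) stop("occurrenceRate: empty input")
  100 * mean(efficiencies >= v)
}

#' Per-measure best over a set of evaluated networks
#'
#' Column-wise maximum of the four measures across networks — the "best
#' performance" summary of a benchmark run.
#'
#' @param metricFrame data.frame or matrix with columns `accuracy`,
#'   `tpr`, `tnr`, `f` (one row per network).
#' @return Named numeric vector of per-measure maxima.
#' @export
bestMetrics <- function(metricFrame) {
  m <- as.data.frame(metricFrame)[, c("accuracy", "tpr", "tnr", "f")]
  if (!nrow(m)) stop("bestMetrics: empty input")
  vapply(m, max, numeric(1))
}

#' Spearman rank correlation
#'
#' Rank-based correlation with average ranks for ties; the nonlinear
#' association measure used to show that retained triplets often join OTU
#' pairs invisible to correlation screens.
#'
#' @param x,y equal-length numeric series (length >= 3).
#' @return Correlation in \[-1, 1\].
#' @export
spearmanRho <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("spearmanRho: need equal-length series of length >= 3")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    stop("spearmanRho: constant series")
  cor(x, y, method = "spearman")
}

#' Pr percentage from its counts
#'
#' The Pr statistic summarizes how often the regulator-target pairs of
#' true-positive-bearing triplets have low rank correlation:
#' `pr = (omOtCount + ocOtCount) * 100 / totalCount`.
#'
#' @param omOtCount triplets whose true cooperative pair has Spearman rho
#'   below the cut.
#' @param ocOtCount triplets whose true competitive pair has rho above the
#'   negated cut.
#' @param totalCount triplets carrying at least one true-positive link.
#' @return Pr as a percentage.
#' @examples
#' prValue(3, 3, 26)  # 23.1 (1 d.p.)
#' @export
prValue <- function(omOtCount, ocOtCount, totalCount) {
  stopifnot(totalCount > 0)
  (omOtCount + ocOtCount) * 100 / totalCount
}

#' Low-correlation analysis of retained triplets
#'
#' Among retained triplets that carry at least one true-positive link,
#' counts those whose cooperative pair `(m, t)` is a true link with
#' Spearman rho below `rhoCut`, and those whose competitive pair `(c, t)`
#' is a true link with rho above `-rhoCut` — pairs whose correlation is
#' too weak (in the expected direction) for a correlation screen to flag.
#'
#' @param triplets retained triplet data.frame (from [filterTriplets()]).
#' @param x the [SRPMatrix] (or matrix) the triplets were scored on.
#' @param truth the ground-truth [RegulatoryNetwork].
#' @param rhoCut correlation cut (default 0.5).
#' @return A list with `omOtCount`, `ocOtCount`, `totalCount`, `prValue`
#'   (`NA` when no triplet bears a true-positive link).
#' @export
prAnalysis <- function(triplets, x, truth, rhoCut = 0.5) {
  P <- .as_srp_values(x)
  tEdges <- edges(truth)
  key <- paste(tEdges$source, tEdges$target, tEdges$sign)
  coopTP <- paste(triplets$m, triplets$t, "cooperative") %in% key
  compTP <- paste(triplets$c, triplets$t, "competitive") %in% key
  bearing <- coopTP | compTP
  om <- 0L; oc <- 0L
  for (i in which(coopTP)) {
    if (spearmanRho(P[triplets$m[i], ], P[triplets$t[i], ]) < rhoCut)
      om <- om + 1L
  }
  for (i in which(compTP)) {
    if (spearmanRho(P[triplets$c[i], ], P[triplets$t[i], ]) > -rhoCut)
      oc <- oc + 1L
  }
  total <- sum(bearing)
  list(omOtCount = om, ocOtCount = oc, totalCount = total,
       prValue = if (total > 0) prValue(om, oc, total) else NA_real_)
}

# Truth as a logical signed-link vector over O1..O10.
.benchmark_truth_vector <- function() {
  net <- groundTruthNetwork()
  .edge_link_vector(edges(net), nodes(net))
}

# Confusion + metrics for one scored dataset at given thresholds, using
# the union-link semantics of tripletLinks() in vectorized form.
.evaluate_scores <- function(sc, ldMax, dMax, truthVec, n) {
  keep <- sc$Ld >= 0 & sc$Ld <= ldMax & sc$D < dMax
  pv <- logical(2L * n * n)
  pv[.link_ids(sc$m[keep], sc$t[keep], 0L, n)] <- TRUE
  pv[.link_ids(sc$c[keep], sc$t[keep], 1L, n)] <- TRUE
  universe <- 2L * n * (n - 1L)
  tp <- sum(pv & truthVec)
  fp <- sum(pv) - tp
  fn <- sum(truthVec) - tp
  tn <- universe - tp - fp - fn
  tpr <- tp / (tp + fn)
  tnr <- tn / (tn + fp)
  f <- if (tpr + tnr == 0) 0 else 2 * tpr * tnr / (tpr + tnr)
  c(accuracy = (tp + tn) / universe, tpr = tpr, tnr = tnr, f = f,
    tp = tp, fp = fp, tn = tn, fn = fn, nRetained = sum(keep))
}

#' Re-evaluate one SRP matrix at given thresholds
#'
#' Scores all triplets of `x`, filters at (`ldMax`, `dMax`), expands the
#' retained triplets into their signed links ([tripletLinks()] semantics)
#' and scores them against the ground truth. Used to re-examine a single
#' benchmark dataset — e.g. the best-performing one — across threshold
#' settings.
#'
#' @inheritParams prAnalysis
#' @inheritParams filterTriplets
#' @inheritParams scanTriplets
#' @return Named numeric vector: the four measures, `efficiency`, the
#'   confusion counts and `nRetained`.
#' @export
evaluateDataset <- function(x, ldMax = 0.8, dMax = 0.8,
                            truth = groundTruthNetwork(),
                            scheme = c("anchored", "refit")) {
  scheme <- match.arg(scheme)
  P <- .as_srp_values(x)
  ids <- if (is.null(rownames(P))) as.character(seq_len(nrow(P))) else rownames(P)
  nodeIds <- nodes(truth)
  if (!setequal(ids, nodeIds))
    stop("evaluateDataset: OTU ids do not match the truth network nodes")
  P <- P[nodeIds, , drop = FALSE]
  sc <- .score_all_triplets(P, scheme)
  tv <- .edge_link_vector(edges(truth), nodeIds)
  out <- .evaluate_scores(sc, ldMax, dMax, tv, length(nodeIds))
  c(out, efficiency = efficiencyScore(out))
}

#' Run the simulation benchmark
#'
#' Simulates `nNetworks` independent ten-OTU communities at one noise
#' regime, min-max standardizes each, scores all 720 ordered triplets,
#' filters at the given thresholds, and scores the implied signed links
#' against the 14-edge ground truth over the 180-candidate universe.
#'
#' @param nNetworks number of simulated communities (benchmark: 5000).
#' @param nTimepoints time points per community (benchmark: 13).
#' @param noise noise regime (`"none"`, `"low"`, `"medium"`, `"high"`).
#' @param ldMax,dMax reliability thresholds (see [filterTriplets()]).
#' @param seed integer seed for the whole run.
#' @inheritParams scanTriplets
#' @param keepBest retain the SRP matrix of the best dataset (highest
#'   efficiency, ties broken by accuracy, then TPR, then simulation order)
#'   for follow-up re-evaluation at other thresholds. Efficiency is used
#'   for the selection because a near-empty prediction can reach high
#'   accuracy and TNR on a sparse truth while recovering nothing.
#' @return A list with `metrics` (data.frame, one row per network:
#'   measures, efficiency, confusion counts, `nRetained`), `best`
#'   (per-measure maxima), `bestEfficiency`, `bestIndex`, `bestSRP`
#'   (matrix or `NULL`), and the run settings.
#' @examples
#' b <- runBenchmark(20, noise = "none", seed = 7)
#' b$best
#' @export
runBenchmark <- function(nNetworks = 5000L, nTimepoints = 13L,
                         noise = c("none", "low", "medium", "high"),
                         ldMax = 0.8, dMax = 0.8, seed = NULL,
                         keepBest = TRUE, scheme = c("anchored", "refit")) {
  noise <- match.arg(noise)
  scheme <- match.arg(scheme)
  if (!is.null(seed)) set.seed(seed)
  truthVec <- .benchmark_truth_vector()
  n <- 10L
  res <- matrix(NA_real_, nNetworks, 9L)
  colnames(res) <- c("accuracy", "tpr", "tnr", "f", "tp", "fp", "tn", "fn",
                     "nRetained")
  eff <- numeric(nNetworks)
  bestIdx <- NA_integer_
  bestKey <- c(-Inf, -Inf, -Inf)
  bestSRP <- NULL
  nDegenerate <- 0L
  for (i in seq_len(nNetworks)) {
    # Reject draws whose clipped abundances are constant for some OTU
    # (no temporal signal, not standardizable); these are rare (~1e-4).
    repeat {
      sim <- .simulate_core(as.integer(nTimepoints), noise)
      lo <- apply(sim$O, 1L, min)
      hi <- apply(sim$O, 1L, max)
      if (all(hi > lo)) break
      nDegenerate <- nDegenerate + 1L
    }
    P <- (sim$O - lo) / (hi - lo)
    sc <- .score_all_triplets(P, scheme)
    r <- .evaluate_scores(sc, ldMax, dMax, truthVec, n)
    res[i, ] <- r
    eff[i] <- sort(r[c("accuracy", "tpr", "tnr", "f")], decreasing = TRUE)[3L]
    key <- c(eff[i], r[["accuracy"]], r[["tpr"]])
    better <- key[1L] > bestKey[1L] ||
      (key[1L] == bestKey[1L] && key[2L] > bestKey[2L]) ||
      (key[1L] == bestKey[1L] && key[2L] == bestKey[2L] && key[3L] > bestKey[3L])
    if (better) {
      bestKey <- key; bestIdx <- i
      if (keepBest) bestSRP <- P
    }
  }
  metrics <- as.data.frame(res)
  metrics$efficiency <- eff
  list(metrics = metrics, best = bestMetrics(metrics),
       bestEfficiency = max(eff), bestIndex = bestIdx, bestSRP = bestSRP,
       nDegenerate = nDegenerate,
       settings = list(nNetworks = nNetworks, nTimepoints = nTimepoints,
                       noise = noise, ldMax = ldMax, dMax = dMax,
                       seed = seed, scheme = scheme))
}
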