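#' @importFrom utils head
NULL

# Precomputed enumeration of ordered (m, c, t) triples for n OTUs, plus the
# (m, c) pair index each triplet points into. Cached per n.
.triplet_index_cache <- new.env(parent = emptyenv())

.triplet_index <- function(n) {
  key <- as.character(n)
  idx <- .triplet_index_cache[[key]]
  if (!is.null(idx)) return(idx)
  pairs <- expand.grid(c = seq_len(n), m = seq_len(n))[, c("m", "c")]
  pairs <- pairs[pairs$m != pairs$c, , drop = FALSE]
  npair <- nrow(pairs)
  t_all <- rep(seq_len(n), each = npair)
  pair_all <- rep(seq_len(npair), times = n)
  keep <- t_all != pairs$m[pair_all] & t_all != pairs$c[pair_all]
  idx <- list(pair_m = pairs$m, pair_c = pairs$c,
              pair = pair_all[keep], t = t_all[keep])
  idx$m <- idx$pair_m[idx$pair]
  idx$c <- idx$pair_c[idx$pair]
  ord <- order(idx$m, idx$c, idx$t)
  idx$pair <- idx$pair[ord]; idx$t <- idx$t[ord]
  idx$m <- idx$m[ord]; idx$c <- idx$c[ord]
  .triplet_index_cache[[key]] <- idx
  idx
}

# Vectorized scoring of all ordered triplets of an SRP matrix (rows = OTUs,
# columns = time points). Returns a list of numeric vectors of length
# n(n-1)(n-2). The per-triplet arithmetic mirrors lackOfFit /
# leaveOneOutLackOfFit / adjustmentScore exactly.
.score_all_triplets <- function(P, scheme = "anchored") {
  n <- nrow(P)
  k <- ncol(P)
  if (n < 3L) stop("scanTriplets: need at least 3 OTUs")
  if (k < 3L) stop("scanTriplets: need at least 3 time points")
  idx <- .triplet_index(n)

  pred <- modelSurface(P[idx$pair_m, , drop = FALSE],
                       P[idx$pair_c, , drop = FALSE])
  dim(pred) <- c(length(idx$pair_m), k)

  s1 <- rowSums(P)
  s2 <- rowSums(P * P)
  ss <- s2 - s1^2 / k                      # full sum of squared deviations
  if (any(ss <= 1e-300)) {
    bad <- rownames(P)[ss <= 1e-300]
    if (is.null(bad)) bad <- which(ss <= 1e-300)
    stop("scanTriplets: degenerate (constant) target series for OTU(s) ",
         paste(bad, collapse = ", "))
  }
  # leave-one-out SS of the target: recomputed mean ("refit") or the
  # full-series SS kept fixed ("anchored")
  ss_loo <- if (scheme == "refit")
    (s2 - P^2) - (s1 - P)^2 / (k - 1)
  else
    matrix(ss, n, k)

  R <- P[idx$t, , drop = FALSE] - pred[idx$pair, , drop = FALSE]
  R2 <- R * R
  num <- rowSums(R2)
  L <- num / ss[idx$t]

  num_loo <- num - R2
  den_loo <- ss_loo[idx$t, , drop = FALSE]
  degen <- den_loo <= 1e-300
  den_loo[degen] <- NA_real_
  ratio <- (num_loo / den_loo) / L
  term <- abs(ratio * log10(ratio))
  term[!is.na(ratio) & ratio == 0] <- 0
  term[is.na(term)] <- 0                    # skipped degenerate terms
  D <- rowSums(term)
  D[L == 0] <- 0

  list(m = idx$m, c = idx$c, t = idx$t, L = L, D = D,
       I = L * (1 + D), Ld = ifelse(L >= 1, Inf, L / (1 - L)),
       degenerateLoo = rowSums(degen) > 0)
}

.as_srp_values <- function(x) {
  if (is(x, "SRPMatrix")) srp(x)
  else if (is.matrix(x)) x
  else stop("expected an SRPMatrix or a numeric matrix")
}

#' Score all ordered OTU-triplets
#'
#' Enumerates every ordered triple of distinct OTUs (cooperator `m`,
#' competitor `c`, target `t`) — \eqn{n(n-1)(n-2)} triplets for `n` OTUs —
#' and computes the lack-of-fit `L`, stability adjustment `D`, integrated
#' score `I`, and filter statistic `Ld` for each. Both orientations
#' `(m, c, t)` and `(c, m, t)` are scored: the surface's antisymmetry
#' makes their fits differ, so no de-duplication applies.
#'
#' @param x an [SRPMatrix] (or plain numeric matrix of SRP values, rows =
#'   OTUs, columns = ordered time points). No row may be constant.
#' @param scheme leave-one-out scheme for the stability adjustment, see
#'   [leaveOneOutLackOfFit()].
#' @return A data.frame with one row per triplet: columns `m`, `c`, `t`
#'   (OTU ids), `mIdx`, `cIdx`, `tIdx` (row indices), `L`, `Ld`, `D`, `I`
#'   and `degenerateLoo` (flag: some leave-one-out target was constant and
#'   its term was skipped).
#' @examples
#' set.seed(1)
#' P <- t(apply(matrix(runif(40), 4), 1, function(r) (r - min(r)) / diff(range(r))))
#' nrow(scanTriplets(P))  # 4 * 3 * 2 = 24
#' @export
scanTriplets <- function(x, scheme = c("anchored", "refit")) {
  scheme <- match.arg(scheme)
  P <- .as_srp_values(x)
  ids <- rownames(P)
  if (is.null(ids)) ids <- paste0("OTU", seq_len(nrow(P)))
  sc <- .score_all_triplets(P, scheme)
  data.frame(m = ids[sc$m], c = ids[sc$c], t = ids[sc$t],
             mIdx = sc$m, cIdx = sc$c, tIdx = sc$t,
             L = sc$L, Ld = sc$Ld, D = sc$D, I = sc$I,
             degenerateLoo = sc$degenerateLoo,
             stringsAsFactors = FALSE)
}

#' Filter scored triplets by reliability thresholds
#'
#' Keeps triplets satisfying \eqn{0 \le L_d \le} `ldMax` (inclusive) and
#' \eqn{D <} `dMax` (strict). The thresholds explored on the benchmark are
#' 0.8/1.8/2.8/3.8 for each; 0.8/0.8 gives the best benchmark accuracy
#' while `ldMax = 3.8`, `dMax = 0.8` favours sensitivity on noisy real
#' data.
#'
#' @param triplets data.frame from [scanTriplets()].
#' @param ldMax inclusive upper bound on `Ld`.
#' @param dMax exclusive upper bound on `D`.
#' @return The subset of rows passing both criteria.
#' @export
filterTriplets <- function(triplets, ldMax = 0.8, dMax = 0.8) {
  stopifnot(ldMax >= 0, dMax >= 0)
  triplets[triplets$Ld >= 0 & triplets$Ld <= ldMax & triplets$D < dMax, ,
           drop = FALSE]
}

#' Rank triplets by integrated score
#'
#' Sorts ascending by `I` (smaller = stronger relationship); ties broken
#' by `L` ascending, then by the `(m, c, t)` labels for a fully
#' deterministic order. Adds a `rank` column.
#'
#' @inheritParams filterTriplets
#' @return The reordered data.frame with a `rank` column prepended.
#' @export
rankTriplets <- function(triplets) {
  ord <- order(triplets$I, triplets$L, triplets$m, triplets$c, triplets$t)
  out <- triplets[ord, , drop = FALSE]
  rownames(out) <- NULL
  cbind(rank = seq_len(nrow(out)), out)
}

#' Assemble the regulatory network from retained triplets
#'
#' Each retained triplet `(m, c, t)` contributes exactly two directed
#' signed edges: a cooperative edge `m -> t` and a competitive edge
#' `c -| t`; the cooperator-competitor pair itself contributes none.
#' Duplicate edges across triplets are merged, recording every supporting
#' triplet and the best (smallest) `I` among them. If the same ordered
#' pair is implied with both signs, the default policy is an error listing
#' the conflicting triplets (such a conflict usually indicates overly
#' permissive thresholds); `conflict = "lowestI"` instead keeps the sign
#' of the lowest-`I` supporting triplet.
#'
#' @param triplets filtered (and ideally ranked) triplet data.frame.
#' @param topK optional cap: only the first `topK` rows (by current order)
#'   enter the network. Default uses all rows.
#' @param conflict `"error"` (default) or `"lowestI"`.
#' @return A [RegulatoryNetwork].
#' @export
buildNetwork <- function(triplets, topK = NULL, conflict = c("error", "lowestI")) {
  conflict <- match.arg(conflict)
  if (!is.null(topK)) triplets <- head(triplets, topK)
  nodes <- sort(unique(c(triplets$m, triplets$c, triplets$t)))
  if (!nrow(triplets)) return(RegulatoryNetwork())
  label <- sprintf("(%s,%s,%s)", triplets$m, triplets$c, triplets$t)
  cand <- data.frame(
    source = c(triplets$m, triplets$c),
    target = c(triplets$t, triplets$t),
    sign = rep(c("cooperative", "competitive"), each = nrow(triplets)),
    I = c(triplets$I, triplets$I),
    triplet = c(label, label),
    stringsAsFactors = FALSE)

  pairKey <- paste(cand$source, cand$target, sep = "\r")
  bySign <- split(cand, paste(pairKey, cand$sign, sep = "\r"))
  merged <- do.call(rbind, lapply(bySign, function(g) {
    data.frame(source = g$source[1], target = g$target[1], sign = g$sign[1],
               nSupporting = nrow(g), bestI = min(g$I),
               stringsAsFactors = FALSE)
  }))
  prov <- lapply(bySign, function(g) unique(g$triplet))

  dupPair <- paste(merged$source, merged$target, sep = "\r")
  conflicted <- dupPair[duplicated(dupPair)]
  if (length(conflicted)) {
    if (conflict == "error") {
      bad <- unique(unlist(prov[dupPair %in% conflicted]))
      stop("buildNetwork: ordered pair(s) implied with both signs: ",
           paste(unique(sub("\r", " -> ", conflicted)), collapse = "; "),
           "; supporting triplets: ", paste(bad, collapse = " "))
    }
    keep <- !logical(nrow(merged))
    for (p in unique(conflicted)) {
      at <- which(dupPair == p)
      drop <- at[-which.min(merged$bestI[at])]
      keep[drop] <- FALSE
    }
    merged <- merged[keep, , drop = FALSE]
    prov <- prov[keep]
  }

  ord <- order(merged$source, merged$target, merged$sign)
  merged <- merged[ord, , drop = FALSE]
  rownames(merged) <- NULL
  RegulatoryNetwork(nodes = nodes, edges = merged, provenance = prov[ord])
}
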