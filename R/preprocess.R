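#' @importFrom stats sd
NULL

#' Convert counts to per-time-point relative proportions
#'
#' Divides each count by its column total over non-missing entries:
#' \eqn{X_{ij} = Y_{ij} / Y_j}. Missing entries stay missing; every column
#' of proportions sums to 1 over its observed entries.
#'
#' @param table an [AbundanceTable].
#' @return A [ProportionTable].
#' @export
relativeAbundance <- function(table) {
  stopifnot(is(table, "AbundanceTable"))
  Y <- counts(table)
  m <- missingMask(table)
  tot <- colSums(Y, na.rm = TRUE)
  zero <- tot <= 0
  if (any(zero))
    stop("relativeAbundance: zero total count at time point(s): ",
         paste(colnames(Y)[zero], collapse = ", "))
  X <- sweep(Y, 2L, tot, "/")
  ProportionTable(X, taxonomy = taxonomy(table), missing = m)
}

#' Prevalence filter for OTUs
#'
#' Drops OTUs observed (non-missing count > 0) at fewer than
#' `minFraction` of the total time points; "fewer than" is strict, so an
#' OTU present at exactly the fraction is kept. Row order of survivors is
#' preserved.
#'
#' @param table an [AbundanceTable].
#' @param minFraction required fraction of time points, in (0, 1\].
#' @return The filtered [AbundanceTable] (warning if no OTU survives).
#' @export
filterOTUsByPrevalence <- function(table, minFraction = 0.5) {
  stopifnot(is(table, "AbundanceTable"), minFraction > 0, minFraction <= 1)
  Y <- counts(table)
  m <- missingMask(table)
  present <- rowSums(Y > 0 & !m, na.rm = TRUE)
  keep <- present >= minFraction * ncol(Y)
  if (!any(keep))
    warning("filterOTUsByPrevalence: no OTU passes the prevalence filter")
  table[keep, ]
}

.row_cv <- function(X, m) {
  vapply(seq_len(nrow(X)), function(i) {
    x <- X[i, !m[i, ]]
    mu <- mean(x)
    if (mu == 0) Inf else sd(x) / mu
  }, numeric(1))
}

#' Abundance/variability filter for OTUs
#'
#' Removes OTU `l` iff its maximum proportion is below `maxProp` AND its
#' coefficient of variation (sd/mean over non-missing entries) exceeds
#' `cvMax` — i.e. rare and erratic. An all-zero row has CV treated as
#' `+Inf` (and max 0), so dead rows are removed.
#'
#' @param props a [ProportionTable].
#' @param maxProp maximum-proportion cut (default 0.1).
#' @param cvMax coefficient-of-variation cut (default 3.4).
#' @return The filtered [ProportionTable].
#' @export
filterOTUsByAbundance <- function(props, maxProp = 0.1, cvMax = 3.4) {
  stopifnot(is(props, "ProportionTable"))
  X <- props(props)
  m <- missingMask(props)
  maxima <- apply(ifelse(m, -Inf, X), 1L, max, na.rm = TRUE)
  cv <- .row_cv(X, m)
  drop <- maxima < maxProp & cv > cvMax
  if (all(drop))
    warning("filterOTUsByAbundance: no OTU passes the abundance filter")
  props[!drop, ]
}

#' Low-signal time-point filter
#'
#' Removes time point `k` iff no OTU reaches `maxProp` there AND fewer
#' than `otuFraction` of the OTUs have a non-zero, non-missing value at
#' `k`.
#'
#' @inheritParams filterOTUsByAbundance
#' @param otuFraction required fraction of observed OTUs (default 0.6).
#' @return The filtered [ProportionTable]; removing every time point is an
#'   error.
#' @export
filterTimePoints <- function(props, maxProp = 0.1, otuFraction = 0.6) {
  stopifnot(is(props, "ProportionTable"))
  X <- props(props)
  m <- missingMask(props)
  maxima <- apply(ifelse(m, -Inf, X), 2L, max, na.rm = TRUE)
  frac <- colSums(X > 0 & !m, na.rm = TRUE) / nrow(X)
  drop <- maxima < maxProp & frac < otuFraction
  if (all(drop))
    stop("filterTimePoints: every time point fails the filter")
  props[, !drop]
}

# Iterative EM-style PCA imputation on a numeric matrix with NAs: missing
# cells start at their column means and are refined by successive rank-K
# SVD reconstructions (centered on row means) until the imputed values
# change by less than `tol` (RMS) or `maxIter` is hit.
.em_pca_impute <- function(X, K, maxIter, tol) {
  miss <- is.na(X)
  colMu <- colMeans(X, na.rm = TRUE)
  if (anyNA(colMu))
    stop("imputeMissing: a time point has no observed values")
  Z <- X
  Z[miss] <- colMu[col(X)[miss]]
  for (iter in seq_len(maxIter)) {
    mu <- rowMeans(Z)
    C <- Z - mu
    sv <- svd(C, nu = K, nv = K)
    fit <- sv$u %*% (sv$d[seq_len(K)] * t(sv$v)) + mu
    delta <- sqrt(mean((fit[miss] - Z[miss])^2))
    Z[miss] <- fit[miss]
    if (delta < tol) return(list(values = Z, iterations = iter, converged = TRUE))
  }
  warning("imputeMissing: EM-PCA did not converge in ", maxIter,
          " iterations; returning the current estimate")
  list(values = Z, iterations = maxIter, converged = FALSE)
}

#' Impute missing proportions by iterative principal-component analysis
#'
#' Fills missing entries with an EM-style probabilistic-PCA scheme:
#' missing cells are initialized at their column (time point) means, then
#' repeatedly replaced by the rank-`nComponents` SVD reconstruction of the
#' row-centered matrix until the imputed values stabilize. Observed
#' entries are never altered; imputed values are clipped to \[0, 1\]. The
#' interface is deliberately minimal so a different imputation engine can
#' stand behind it.
#'
#' @param props a [ProportionTable] (possibly with missing entries).
#' @param nComponents number of principal components `K` (default 5).
#' @param maxIter iteration cap (default 500).
#' @param tol convergence tolerance on the RMS change of imputed values.
#' @return A complete [ProportionTable] with an all-`FALSE` missing mask.
#' @export
imputeMissing <- function(props, nComponents = 5L, maxIter = 500L, tol = 1e-6) {
  stopifnot(is(props, "ProportionTable"))
  X <- props(props)
  m <- missingMask(props)
  if (!any(m)) return(props)
  if (mean(m) >= 0.5)
    stop("imputeMissing: more than half of the entries are missing")
  K <- as.integer(nComponents)
  if (K < 1L || K > min(dim(X)) - 1L)
    stop("imputeMissing: nComponents must be in [1, min(dim) - 1]")
  X[m] <- NA_real_
  fit <- .em_pca_impute(X, K, maxIter, tol)
  Z <- fit$values
  Z[m] <- pmin(pmax(Z[m], 0), 1)
  Z[!m] <- X[!m]
  ProportionTable(Z, taxonomy = taxonomy(props),
                  missing = matrix(FALSE, nrow(Z), ncol(Z)))
}

#' Standardize proportions to per-OTU SRPs
#'
#' Min-max scales every OTU row: \eqn{P_{ij} = (X_{ij} - X_{\min}) /
#' (X_{\max} - X_{\min})} with the row minimum and maximum, so each OTU
#' spans \[0, 1\] across time. This per-OTU scaling is what lets a rare
#' OTU still express "high" and "low" regimes for the triplet rule. A
#' constant row has no min-max scale and cannot participate in any triplet
#' meaningfully; it is reported as an error so the caller removes it.
#'
#' @param props a complete [ProportionTable] (no missing entries; run
#'   [imputeMissing()] first).
#' @return An [SRPMatrix].
#' @export
standardizeSRP <- function(props) {
  stopifnot(is(props, "ProportionTable"))
  if (any(missingMask(props)))
    stop("standardizeSRP: missing entries present; impute first")
  X <- props(props)
  rng <- apply(X, 1L, range)
  span <- rng[2L, ] - rng[1L, ]
  if (any(span <= 0))
    stop("standardizeSRP: constant-abundance OTU(s) ",
         paste(rownames(X)[span <= 0], collapse = ", "),
         "; remove them before standardization")
  SRPMatrix((X - rng[1L, ]) / span, taxonomy = taxonomy(props))
}

#' Full preprocessing pipeline
#'
#' Runs the fixed preprocessing order on a raw count table: prevalence
#' filter, relative abundance, abundance/CV filter, time-point filter,
#' imputation, then SRP standardization. OTUs left constant after
#' imputation are dropped (with a message) before standardization.
#'
#' @param table an [AbundanceTable] of raw counts.
#' @param minFraction,maxProp,cvMax,otuFraction,nComponents,maxIter,tol
#'   parameters passed to the individual steps.
#' @return An [SRPMatrix] ready for [scanTriplets()].
#' @export
preprocessPipeline <- function(table, minFraction = 0.5, maxProp = 0.1,
                               cvMax = 3.4, otuFraction = 0.6,
                               nComponents = 5L, maxIter = 500L, tol = 1e-6) {
  x <- filterOTUsByPrevalence(table, minFraction)
  x <- relativeAbundance(x)
  x <- filterOTUsByAbundance(x, maxProp, cvMax)
  x <- filterTimePoints(x, maxProp, otuFraction)
  if (any(missingMask(x)))
    x <- imputeMissing(x, nComponents, maxIter, tol)
  X <- props(x)
  span <- apply(X, 1L, function(r) diff(range(r)))
  if (any(span <= 0)) {
    message("dropping constant-abundance OTU(s): ",
            paste(rownames(X)[span <= 0], collapse = ", "))
    x <- x[span > 0, ]
  }
  standardizeSRP(x)
}
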