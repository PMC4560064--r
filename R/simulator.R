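#' @importFrom stats runif rnorm var setNames
NULL

# Coefficients of the benchmark community: each OTU's abundance is a tanh
# of a linear combination of upstream OTUs (O), latent factors (F) and an
# intercept, scaled by `gain`, plus additive noise.
.SIM_MODEL <- list(
  list(gain = 1.3, O = c(),                       F = c(F2 = -0.1),  b = 0.25),
  list(gain = 1.1, O = c(),                       F = c(F2 = 0.35),  b = 0.10),
  list(gain = 1.0, O = c(O1 = -0.56),             F = c(F1 = 0.4),   b = 0.50),
  list(gain = 1.0, O = c(O1 = 0.6, O2 = -0.15, O3 = -0.1), F = c(), b = 0.10),
  list(gain = 1.0, O = c(O2 = 0.24, O3 = -0.75),  F = c(F1 = -0.05), b = 0.30),
  list(gain = 1.4, O = c(O5 = 0.2, O3 = -0.2),    F = c(),           b = 0.15),
  list(gain = 1.3, O = c(O5 = -0.15),             F = c(),           b = 0.20),
  list(gain = 1.0, O = c(),                       F = c(F3 = -0.15), b = 0.20),
  list(gain = 1.0, O = c(O6 = -0.41, O7 = 0.55, O8 = 0.35), F = c(), b = 0.18),
  list(gain = 1.0, O = c(O7 = -0.45, O8 = 0.7),   F = c(F3 = 0.1),   b = 0.25))

.SIM_OTU_IDS <- paste0("O", 1:10)

#' Ground-truth network of the benchmark community
#'
#' The 14 inter-OTU edges implied by the coefficient signs of the
#' ten-equation benchmark model: a positive coefficient of OTU `a` in the
#' equation of OTU `b` is a cooperative edge `a -> b`, a negative one a
#' competitive edge `a -| b`. Latent-factor inputs are unobserved and
#' contribute no edges.
#'
#' @return A [RegulatoryNetwork] over OTUs `O1`..`O10` with 14 edges.
#' @examples
#' nrow(edges(groundTruthNetwork()))  # 14
#' @export
groundTruthNetwork <- function() {
  src <- character(); tgt <- character(); sgn <- character()
  for (i in seq_along(.SIM_MODEL)) {
    co <- .SIM_MODEL[[i]]$O
    if (!length(co)) next
    src <- c(src, names(co))
    tgt <- c(tgt, rep(.SIM_OTU_IDS[i], length(co)))
    sgn <- c(sgn, ifelse(co > 0, "cooperative", "competitive"))
  }
  e <- data.frame(source = src, target = tgt, sign = sgn,
                  nSupporting = 1L, bestI = NA_real_,
                  stringsAsFactors = FALSE)
  ord <- order(e$source, e$target, e$sign)
  e <- e[ord, , drop = FALSE]
  rownames(e) <- NULL
  RegulatoryNetwork(nodes = .SIM_OTU_IDS, edges = e,
                    provenance = rep(list(character()), nrow(e)))
}

#' Noiseless benchmark abundances from latent draws
#'
#' Evaluates the ten-OTU cascade on a given latent-factor matrix with no
#' noise: rows are computed in order `O1`..`O10`, each a scaled tanh of
#' its upstream OTUs, latent factors and intercept.
#'
#' @param latent numeric 3 x T matrix of latent-factor values in \[0, 1\]
#'   (rows `F1`, `F2`, `F3`).
#' @return A 10 x T matrix of noiseless abundances.
#' @examples
#' abundanceModel(matrix(0, 3, 1))[1, ]  # 1.3 * tanh(0.25)
#' @export
abundanceModel <- function(latent) {
  latent <- as.matrix(latent)
  stopifnot(nrow(latent) == 3L)
  rownames(latent) <- c("F1", "F2", "F3")
  O <- matrix(0, 10L, ncol(latent),
              dimnames = list(.SIM_OTU_IDS, colnames(latent)))
  for (i in seq_along(.SIM_MODEL)) {
    m <- .SIM_MODEL[[i]]
    z <- rep(m$b, ncol(latent))
    for (nm in names(m$O)) z <- z + m$O[[nm]] * O[nm, ]
    for (nm in names(m$F)) z <- z + m$F[[nm]] * latent[nm, ]
    O[i, ] <- m$gain * tanh(z)
  }
  O
}

#' Noise scale for a simulated OTU series
#'
#' The additive noise attached to each OTU is zero-mean Gaussian whose
#' scale derives from the OTU's noiseless series variance and its integer
#' signal-to-noise ratio: `low` = variance / snr, `medium` = 5 x low,
#' `high` = 10 x low, `none` = 0.
#'
#' @param otuVariance variance of the noiseless abundance series.
#' @param snr integer signal-to-noise ratio (4-12 on the benchmark).
#' @param level one of `"none"`, `"low"`, `"medium"`, `"high"`.
#' @return The Gaussian scale (standard deviation) for the noise term.
#' @examples
#' noiseSigma(0.08, 8, "low")   # 0.01
#' noiseSigma(0.08, 8, "high")  # 0.1
#' @export
noiseSigma <- function(otuVariance, snr, level = c("none", "low", "medium", "high")) {
  level <- match.arg(level)
  stopifnot(otuVariance >= 0, snr >= 1)
  base <- otuVariance / snr
  switch(level, none = 0, low = base, medium = 5 * base, high = 10 * base)
}

#' Draw per-OTU signal-to-noise ratios
#'
#' Integers drawn uniformly from `snrRange` (benchmark default 4-12), one
#' per OTU, from the current RNG stream.
#'
#' @param nOtus number of OTUs.
#' @param snrRange integer vector of candidate SNR values.
#' @return Integer vector of length `nOtus`.
#' @export
sampleSnr <- function(nOtus = 10L, snrRange = 4:12) {
  as.integer(sample(snrRange, nOtus, replace = TRUE))
}

#' Simulate one benchmark dataset
#'
#' Generates a ten-OTU community over `nTimepoints` samples: latent
#' factors are i.i.d. Uniform(0, 1); abundances follow the tanh cascade in
#' order `O1`..`O10` so that noise on an upstream OTU propagates
#' downstream; each OTU's additive noise is Gaussian with scale
#' [noiseSigma()] computed from the variance of its noiseless series and a
#' freshly drawn SNR; each noisy row is clipped to \[0, 1\] before feeding
#' the rows below it. Fully reproducible from `seed`.
#'
#' @param nTimepoints number of time points (benchmark: 13).
#' @param noise noise regime: `"none"`, `"low"`, `"medium"` or `"high"`.
#' @param seed optional integer seed; `NULL` uses the current RNG state.
#' @param snrRange integer SNR support (default 4:12).
#' @return A [SimulatedDataset-class] object.
#' @examples
#' d <- simulateDataset(13, noise = "low", seed = 42)
#' dim(abundances(d))
#' @export
simulateDataset <- function(nTimepoints = 13L, noise = c("none", "low", "medium", "high"),
                            seed = NULL, snrRange = 4:12) {
  noise <- match.arg(noise)
  stopifnot(nTimepoints >= 3L)
  if (!is.null(seed)) set.seed(seed)
  sim <- .simulate_core(as.integer(nTimepoints), noise, snrRange)
  latent <- sim$latent; snr <- sim$snr; N <- sim$N; O <- sim$O
  new("SimulatedDataset", abundances = O, latent = latent, noise = N,
      snr = snr, truth = groundTruthNetwork(),
      config = list(nTimepoints = as.integer(nTimepoints), noise = noise,
                    seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
                    snrRange = snrRange))
}

# Draws one dataset from the current RNG stream; plain matrices, no S4.
# Model indices/coefficients are pre-flattened for speed.
.SIM_FLAT <- local({
  lapply(.SIM_MODEL, function(m) {
    list(gain = m$gain, b = m$b,
         oIdx = match(names(m$O), .SIM_OTU_IDS), oCoef = unname(unlist(m$O)),
         fIdx = match(names(m$F), c("F1", "F2", "F3")),
         fCoef = unname(unlist(m$F)))
  })
})

.NOISE_MULT <- c(none = 0, low = 1, medium = 5, high = 10)

.simulate_core <- function(k, noise, snrRange = 4:12) {
  latent <- matrix(runif(3L * k), 3L, k,
                   dimnames = list(c("F1", "F2", "F3"), paste0("S", seq_len(k))))
  snr <- as.integer(sample(snrRange, 10L, replace = TRUE))
  mult <- .NOISE_MULT[[noise]]
  # noiseless pass (unclipped), for the per-OTU variance the noise scale uses
  O0 <- matrix(0, 10L, k)
  for (i in 1:10) {
    m <- .SIM_FLAT[[i]]
    z <- m$b
    if (length(m$oIdx)) z <- z + drop(m$oCoef %*% O0[m$oIdx, , drop = FALSE])
    if (length(m$fIdx)) z <- z + drop(m$fCoef %*% latent[m$fIdx, , drop = FALSE])
    O0[i, ] <- m$gain * tanh(z)
  }
  v <- rowSums((O0 - rowMeans(O0))^2) / (k - 1)
  sig <- mult * v / snr
  N <- matrix(rnorm(10L * k), 10L, k) * sig
  # noisy pass: each row is clipped to [0, 1] before feeding rows below
  O <- matrix(0, 10L, k, dimnames = list(.SIM_OTU_IDS, colnames(latent)))
  for (i in 1:10) {
    m <- .SIM_FLAT[[i]]
    z <- m$b
    if (length(m$oIdx)) z <- z + drop(m$oCoef %*% O[m$oIdx, , drop = FALSE])
    if (length(m$fIdx)) z <- z + drop(m$fCoef %*% latent[m$fIdx, , drop = FALSE])
    O[i, ] <- pmin(pmax(m$gain * tanh(z) + N[i, ], 0), 1)
  }
  dimnames(N) <- dimnames(O)
  list(latent = latent, snr = snr, N = N, O = O)
}

# Per-row min-max scaling of a plain matrix (hot-loop variant of
# simulatedSRP without S4 validation).
.minmax_rows <- function(A) {
  lo <- apply(A, 1L, min)
  hi <- apply(A, 1L, max)
  span <- hi - lo
  if (any(span <= 0))
    stop("constant abundance row(s): ",
         paste(rownames(A)[span <= 0], collapse = ", "))
  (A - lo) / span
}

#' Min-max standardize simulated abundances to SRPs
#'
#' Applies the same per-OTU min-max standardization used on real data to a
#' simulated abundance matrix, so benchmark datasets run through the same
#' scanning path.
#'
#' @param x a [SimulatedDataset-class] or a numeric abundance matrix.
#' @return An [SRPMatrix].
#' @export
simulatedSRP <- function(x) {
  A <- if (is(x, "SimulatedDataset")) abundances(x) else as.matrix(x)
  rng <- apply(A, 1L, range)
  span <- rng[2L, ] - rng[1L, ]
  if (any(span <= 0))
    stop("simulatedSRP: constant abundance row(s): ",
         paste(rownames(A)[span <= 0], collapse = ", "))
  SRPMatrix((A - rng[1L, ]) / span)
}
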