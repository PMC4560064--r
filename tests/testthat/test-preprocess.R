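make_counts <- function(mat, ...) AbundanceTable(mat, ...)

test_that("relative abundance divides by per-time-point totals", {
  ab <- make_counts(matrix(c(2, 3, 5,
                             7, 0, 0), nrow = 3, byrow = FALSE,
                           dimnames = list(c("a", "b", "c"), c("t1", "t2"))))
  pr <- relativeAbundance(ab)
  expect_equal(unname(props(pr)[, 1]), c(0.2, 0.3, 0.5))
  expect_equal(unname(props(pr)[, 2]), c(1, 0, 0))

  ab2 <- make_counts(matrix(c(1, 3, 9, 1), 2,
                            dimnames = list(c("a", "b"), c("t1", "t2"))))
  expect_equal(unname(props(relativeAbundance(ab2))),
               matrix(c(0.25, 0.75, 0.9, 0.1), 2))
})

test_that("relative abundance: columns sum to 1 over observed entries", {
  set.seed(52)
  m <- matrix(rpois(60, 20), 6, 10, dimnames = list(paste0("o", 1:6), paste0("t", 1:10)))
  m[sample(60, 8)] <- NA
  pr <- relativeAbundance(make_counts(m))
  sums <- colSums(props(pr), na.rm = TRUE)
  expect_true(all(abs(sums - 1) < 1e-9))
  # missingness preserved
  expect_identical(missingMask(pr), is.na(m))
})

test_that("relative abundance names a zero-total time point", {
  m <- matrix(c(1, 2, 0, 0), 2, dimnames = list(c("a", "b"), c("ok", "dead")))
  expect_error(relativeAbundance(make_counts(m)), "dead")
})

test_that("prevalence filter keeps the boundary and is idempotent", {
  m <- matrix(0, 3, 10, dimnames = list(c("five", "four", "all"), paste0("t", 1:10)))
  m["five", 1:5] <- 1   # exactly half: kept ('fewer than' is strict)
  m["four", 1:4] <- 1   # below half: removed
  m["all", ] <- 2
  f1 <- filterOTUsByPrevalence(make_counts(m), 0.5)
  expect_identical(otuIds(f1), c("five", "all"))
  expect_identical(otuIds(filterOTUsByPrevalence(f1, 0.5)), otuIds(f1))
})

test_that("abundance/CV filter removes only rare AND erratic OTUs", {
  X <- rbind(steady = c(0.05, 0.06, 0.04),       # rare but stable: kept
             big    = c(0.5, 0.01, 0.01),        # abundant: kept
             dead   = c(0, 0, 0),                # zero row: removed
             spiky  = c(0.002, 0, 0))            # rare, CV > 3.4? no (cv ~ 1.7): kept
  pr <- ProportionTable(X)
  cv <- sd(X[1, ]) / mean(X[1, ])
  expect_lt(cv, 3.4)
  out <- filterOTUsByAbundance(pr)
  expect_identical(otuIds(out), c("steady", "big", "spiky"))
  # idempotent
  expect_identical(otuIds(filterOTUsByAbundance(out)), otuIds(out))
})

test_that("time-point filter drops low-signal sparse columns only", {
  X <- matrix(0.05, 10, 3,
              dimnames = list(paste0("o", 1:10), c("strong", "sparse", "dense")))
  X["o1", "strong"] <- 0.4                 # max >= 0.1: kept
  X[4:10, "sparse"] <- 0                   # max < 0.1 and 3/10 observed: dropped
  # dense: max < 0.1 but 10/10 non-zero: kept
  out <- filterTimePoints(ProportionTable(X))
  expect_identical(timeLabels(out), c("strong", "dense"))
  expect_identical(timeLabels(filterTimePoints(out)), timeLabels(out))
  expect_error(filterTimePoints(ProportionTable(X[, "sparse", drop = FALSE])),
               "every time point")
})

test_that("imputation is the identity on complete tables", {
  set.seed(61)
  X <- matrix(runif(40), 4, 10)
  pr <- ProportionTable(X)
  expect_identical(props(imputeMissing(pr, 2)), props(pr))
})

test_that("imputation recovers a deleted entry of a rank-1 matrix", {
  u <- c(0.9, 0.5, 0.3, 0.7, 0.2, 0.6)
  v <- c(1, 0.8, 0.6, 0.4, 0.2, 0.9, 0.1, 0.3)
  X <- outer(u, v)
  Xm <- X
  Xm[3, 5] <- NA
  out <- imputeMissing(ProportionTable(Xm), nComponents = 1, tol = 1e-10)
  expect_equal(props(out)[3, 5], X[3, 5], tolerance = 1e-6)
  # observed entries bitwise unchanged
  obs <- !is.na(Xm)
  expect_identical(props(out)[obs], X[obs])
})

test_that("imputation agrees with an independent ALS oracle (K = 1)", {
  set.seed(62)
  u <- runif(7, 0.2, 1); v <- runif(9, 0.2, 1)
  X <- outer(u, v); X <- X / max(X)
  miss <- cbind(c(2, 5), c(3, 8))
  Xm <- X; Xm[miss] <- NA
  got <- props(imputeMissing(ProportionTable(Xm), nComponents = 1, tol = 1e-12))
  # oracle: alternating least squares rank-1 fit on observed cells
  a <- rep(1, 7); b <- colMeans(Xm, na.rm = TRUE)
  W <- !is.na(Xm); X0 <- ifelse(W, Xm, 0)
  for (it in 1:500) {
    a <- rowSums(X0 * rep(b, each = 7) * W) / rowSums(rep(b^2, each = 7) * W)
    b <- colSums(X0 * a * W) / colSums(a^2 * W)
  }
  pred <- outer(a, b)
  expect_equal(got[miss], pred[miss], tolerance = 1e-5)
})

test_that("imputed values are clipped to [0, 1] and missing fraction is bounded", {
  set.seed(63)
  X <- matrix(runif(30), 5, 6)
  Xm <- X; Xm[cbind(1:5, 1:5)] <- NA
  out <- imputeMissing(ProportionTable(Xm), nComponents = 1)
  expect_true(all(props(out) >= 0 & props(out) <= 1))
  expect_false(any(missingMask(out)))
  Xbad <- X; Xbad[1:3, ] <- NA
  expect_error(imputeMissing(ProportionTable(Xbad), 2), "half")
})

test_that("non-convergent imputation warns and still returns an estimate", {
  set.seed(64)
  # a structureless matrix with K = 2 can oscillate between SVD solutions;
  # the contract is a warning plus the current best estimate
  X <- matrix(runif(30), 5, 6)
  X[cbind(1:5, 1:5)] <- NA
  expect_warning(out <- imputeMissing(ProportionTable(X), nComponents = 2,
                                      maxIter = 50L),
                 "did not converge")
  expect_false(anyNA(props(out)))
})

test_that("SRP standardization maps rows onto [0, 1] exactly", {
  X <- rbind(a = c(0.2, 0.5, 0.8), b = c(0.1, 0.1, 0.4), c = c(0, 0.3, 1))
  out <- srp(standardizeSRP(ProportionTable(X)))
  expect_equal(unname(out["a", ]), c(0, 0.5, 1))
  expect_equal(unname(out["b", ]), c(0, 0, 1))
  expect_true(all(apply(out, 1, min) == 0))
  expect_true(all(apply(out, 1, max) == 1))
  expect_error(standardizeSRP(ProportionTable(rbind(X, flat = c(0.2, 0.2, 0.2)))),
               "flat")
  # missing entries must be imputed first
  Xm <- X; Xm[1, 1] <- NA
  expect_error(standardizeSRP(ProportionTable(Xm)), "impute")
})

test_that("full pipeline produces a valid SRP matrix from raw counts", {
  set.seed(71)
  base <- rand_srp(6, 12)
  counts <- round(base * 900) + 1
  counts <- rbind(counts, rare = c(rep(0, 11), 2))   # fails prevalence
  rownames(counts) <- c(paste0("o", 1:6), "rare")
  colnames(counts) <- paste0("t", 1:12)
  counts[2, 5] <- NA
  out <- preprocessPipeline(AbundanceTable(counts))
  expect_s4_class(out, "SRPMatrix")
  expect_false("rare" %in% otuIds(out))
  v <- srp(out)
  expect_true(all(apply(v, 1, min) == 0) && all(apply(v, 1, max) == 1))
})
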