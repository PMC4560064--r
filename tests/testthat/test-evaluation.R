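test_that("confusion counts partition the 180-candidate universe", {
  tr <- groundTruthNetwork()
  cc <- confusionCounts(tr, tr)
  expect_equal(cc[c("tp", "fp", "tn", "fn")], list(tp = 14, fp = 0, tn = 166, fn = 0))
  empty <- data.frame(source = character(), target = character(),
                      sign = character())
  cc0 <- confusionCounts(empty, tr)
  expect_equal(cc0[c("tp", "fp", "tn", "fn")], list(tp = 0, fp = 0, tn = 166, fn = 14))
  expect_equal(cc0$universe, 180)
  # sum check on a partial prediction
  pred <- edges(tr)[1:5, ]
  pred2 <- rbind(pred, data.frame(source = "O1", target = "O2",
                                  sign = "cooperative", nSupporting = 1L,
                                  bestI = 0))
  cc2 <- confusionCounts(pred2, tr)
  expect_equal(cc2$tp + cc2$fp + cc2$tn + cc2$fn, 180)
  expect_equal(cc2$tp, 5); expect_equal(cc2$fp, 1)
})

test_that("confusion counting rejects nodes outside the candidate set", {
  tr <- groundTruthNetwork()
  alien <- data.frame(source = "O99", target = "O1", sign = "cooperative")
  expect_error(confusionCounts(alien, tr), "outside")
})

test_that("metrics reproduce the arithmetic of a near-perfect recovery", {
  m <- networkMetrics(list(tp = 13, fn = 1, tn = 142, fp = 24))
  expect_equal(unname(round(m, 3)),
               c(0.861, 0.929, 0.855, 0.890))
  perfect <- networkMetrics(list(tp = 14, fn = 0, tn = 166, fp = 0))
  expect_true(all(perfect == 1))
  none <- networkMetrics(list(tp = 0, fn = 14, tn = 166, fp = 0))
  expect_equal(unname(none), c(166 / 180, 0, 1, 0))
  expect_error(networkMetrics(list(tp = 0, fn = 0, tn = 1, fp = 0)), "positive")
})

test_that("efficiency is the third-largest measure", {
  expect_equal(efficiencyScore(c(accuracy = 1, tpr = 1, tnr = 1, f = 1)), 1)
  expect_equal(efficiencyScore(c(accuracy = 0.9, tpr = 0.8, tnr = 0.7, f = 0.6)), 0.7)
  expect_equal(efficiencyScore(c(accuracy = 0.5, tpr = 0.5, tnr = 0.5, f = 0.1)), 0.5)
})

test_that("occurrence rate and per-measure best behave as summaries", {
  expect_equal(occurrenceRate(rep(1, 5), 0.9), 100)
  expect_equal(occurrenceRate(c(0.1, 0.2), 0.5), 0)
  expect_equal(occurrenceRate(c(0.7, 0.6), 0.64), 50)
  df <- data.frame(accuracy = c(0.9, 0.8), tpr = c(0.7, 0.95),
                   tnr = c(0.5, 0.6), f = c(0.6, 0.7))
  expect_equal(bestMetrics(df),
               c(accuracy = 0.9, tpr = 0.95, tnr = 0.6, f = 0.7))
  expect_equal(bestMetrics(df[1, ]), unlist(df[1, ]))
})

test_that("spearman matches the rank formula and the brute-force oracle", {
  expect_equal(spearmanRho(1:5, 2:6), 1)
  expect_equal(spearmanRho(1:5, 5:1), -1)
  expect_equal(spearmanRho(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  set.seed(91)
  for (i in 1:20) {
    k <- sample(3:20, 1)
    x <- runif(k); y <- runif(k)
    expect_equal(spearmanRho(x, y), oracle_spearman(x, y), tolerance = 1e-12)
  }
  expect_error(spearmanRho(rep(1, 4), 1:4), "constant")
})

test_that("Pr formula reproduces its worked percentages", {
  expect_equal(round(prValue(3, 3, 26), 1), 23.1)
  expect_equal(prValue(0, 0, 10), 0)
  expect_equal(round(prValue(4, 0, 24), 1), 16.7)
})

test_that("Pr analysis counts low-correlation true-positive pairs", {
  set.seed(92)
  d <- simulateDataset(13, "none", seed = 92)
  P <- srp(simulatedSRP(d))
  kept <- filterTriplets(scanTriplets(P), 0.8, 0.8)
  pr <- prAnalysis(kept, P, truth(d))
  expect_gte(pr$totalCount, 0)
  expect_lte(pr$omOtCount + pr$ocOtCount, 2 * pr$totalCount)
  if (pr$totalCount > 0) {
    expect_equal(pr$prValue,
                 (pr$omOtCount + pr$ocOtCount) * 100 / pr$totalCount)
    # recount one side by hand
    e <- edges(truth(d))
    key <- paste(e$source, e$target, e$sign)
    om <- 0
    for (i in seq_len(nrow(kept))) {
      if (paste(kept$m[i], kept$t[i], "cooperative") %in% key &&
          spearmanRho(P[kept$m[i], ], P[kept$t[i], ]) < 0.5)
        om <- om + 1
    }
    expect_equal(pr$omOtCount, om)
  }
})

test_that("relaxing the Ld threshold never lowers TPR or raises TNR", {
  set.seed(93)
  for (nl in c("none", "high")) {
    for (rep in 1:5) {
      d <- simulateDataset(13, nl)
      P <- srp(simulatedSRP(d))
      lds <- c(0.8, 1.8, 2.8, 3.8)
      ev <- t(vapply(lds, function(ld) evaluateDataset(P, ld, 0.8),
                     evaluateDataset(P, 0.8, 0.8)))
      expect_true(all(diff(ev[, "tpr"]) >= 0))
      expect_true(all(diff(ev[, "tnr"]) <= 0))
    }
  }
})

test_that("noiseless recovery beats a size-matched random predictor", {
  set.seed(94)
  b <- runBenchmark(40, noise = "none")
  meanAcc <- mean(b$metrics$accuracy)
  # random predictor with the same average number of predicted links:
  # E[accuracy] = (p * 14 + (1 - p) * 166) / 180 with p = links / 180
  links <- mean(b$metrics$tp + b$metrics$fp)
  p <- links / 180
  randAcc <- (p * 14 + (1 - p) * 166) / 180
  expect_gt(meanAcc, randAcc)
})

test_that("benchmark metrics are internally consistent", {
  set.seed(95)
  b <- runBenchmark(25, noise = "low")
  m <- b$metrics
  expect_equal(nrow(m), 25)
  expect_true(all(m$tp + m$fn == 14))
  expect_true(all(m$tp + m$fp + m$tn + m$fn == 180))
  expect_equal(m$tpr, m$tp / 14)
  expect_equal(m$efficiency,
               apply(m[, c("accuracy", "tpr", "tnr", "f")], 1,
                     function(v) sort(v, decreasing = TRUE)[3]))
  expect_equal(unname(b$best),
               unname(apply(m[, c("accuracy", "tpr", "tnr", "f")], 2, max)))
  expect_true(!is.null(b$bestSRP))
  # the retained best dataset reproduces its recorded metrics
  ev <- evaluateDataset(b$bestSRP, 0.8, 0.8)
  expect_equal(unname(ev["efficiency"]), max(m$efficiency))
})
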