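test_that("scan enumerates n(n-1)(n-2) ordered triplets", {
  set.seed(81)
  expect_equal(nrow(scanTriplets(rand_srp(3, 5))), 6)
  expect_equal(nrow(scanTriplets(rand_srp(5, 5))), 60)
  expect_equal(nrow(scanTriplets(rand_srp(10, 13))), 720)
})

test_that("scan agrees with the three-nested-loop oracle", {
  set.seed(82)
  for (n in c(4, 6)) {
    P <- rand_srp(n, 7)
    got <- scanTriplets(P)
    for (scheme in c("anchored", "refit")) {
      got <- scanTriplets(P, scheme = scheme)
      want <- oracle_scan(P, scheme = scheme)
      key_g <- paste(got$mIdx, got$cIdx, got$tIdx)
      key_w <- paste(want$mIdx, want$cIdx, want$tIdx)
      expect_identical(key_g, key_w)
      expect_equal(got$L, want$L, tolerance = 1e-12)
      expect_equal(got$D, want$D, tolerance = 1e-12)
      expect_equal(got$I, want$I, tolerance = 1e-12)
      expect_equal(got$Ld, want$Ld, tolerance = 1e-12)
    }
  }
})

test_that("a planted surface-generated target scores L = 0, I = 0, rank 1", {
  set.seed(83)
  k <- 10
  coop <- runif(k); comp <- runif(k)
  target <- modelSurface(coop, comp)
  # extra distractor OTUs
  P <- rbind(A = coop, B = comp, T = target, X = runif(k), Y = runif(k))
  # planted rows must be valid SRPs for the scan precondition; rescale
  # distractors only (planting depends on exact coop/comp/target values)
  tr <- scanTriplets(P)
  planted <- tr[tr$m == "A" & tr$c == "B" & tr$t == "T", ]
  expect_equal(planted$L, 0)
  expect_equal(planted$I, 0)
  ranked <- rankTriplets(tr)
  expect_equal(ranked$I[1], 0)
  expect_true(ranked$rank[ranked$m == "A" & ranked$c == "B" & ranked$t == "T"] %in%
                which(ranked$I == 0))
})

test_that("filter applies Ld inclusively and D strictly", {
  tr <- data.frame(m = "a", c = "b", t = "c",
                   L = NA, Ld = c(0.8, 0.81, 0.5, 0.5), D = c(0.79, 0.5, 0.8, 0.79),
                   I = 1)
  kept <- filterTriplets(tr, 0.8, 0.8)
  expect_equal(nrow(kept), 2)            # rows 1 and 4
  expect_true(all(kept$Ld <= 0.8 & kept$D < 0.8))
})

test_that("ranking is ascending in I with documented tie-breaks", {
  tr <- data.frame(m = c("a", "b", "c"), c = c("x", "y", "z"), t = "t",
                   L = c(0.3, 0.1, 0.2), Ld = 0, D = 0, I = c(0.3, 0.1, 0.2))
  expect_identical(rankTriplets(tr)$m, c("b", "c", "a"))
  tie <- data.frame(m = c("a", "b"), c = c("x", "y"), t = "t",
                    L = c(0.2, 0.1), Ld = 0, D = 0, I = c(0.5, 0.5))
  expect_identical(rankTriplets(tie)$m, c("b", "a"))
  single <- tr[1, ]
  expect_identical(rankTriplets(single)$m, "a")
})

test_that("network assembly maps triplets to two signed edges each", {
  tr <- data.frame(m = "A", c = "B", t = "T", L = 0.1, Ld = 0.11, D = 0.2, I = 0.12)
  net <- buildNetwork(tr)
  e <- edges(net)
  expect_equal(nrow(e), 2)
  expect_setequal(nodes(net), c("A", "B", "T"))
  expect_identical(e$sign[e$source == "A"], "cooperative")
  expect_identical(e$sign[e$source == "B"], "competitive")

  tr2 <- rbind(tr, data.frame(m = "C", c = "B", t = "T",
                              L = 0.2, Ld = 0.25, D = 0.1, I = 0.22))
  net2 <- buildNetwork(tr2)
  e2 <- edges(net2)
  expect_equal(nrow(e2), 3)              # A->T, C->T coop; B-|T merged
  expect_equal(length(nodes(net2)), 4)
  bt <- e2[e2$source == "B", ]
  expect_equal(bt$nSupporting, 2L)
  expect_equal(bt$bestI, 0.12)
})

test_that("a star of triplets sharing one target yields the star network", {
  tr <- data.frame(m = c("X", "Y", "Z"), c = "W", t = "T",
                   L = 0.1, Ld = 0.11, D = 0.1, I = c(0.1, 0.2, 0.3))
  net <- buildNetwork(tr)
  e <- edges(net)
  expect_equal(sum(e$sign == "cooperative"), 3)
  expect_equal(sum(e$sign == "competitive"), 1)
  expect_true(all(e$target == "T"))
  expect_equal(length(nodes(net)), 5)
})

test_that("sign conflicts error by default and resolve under lowestI", {
  tr <- data.frame(m = c("A", "B"), c = c("B", "A"), t = "T",
                   L = 0.1, Ld = 0.11, D = 0.1, I = c(0.3, 0.1))
  expect_error(buildNetwork(tr), "both signs")
  net <- buildNetwork(tr, conflict = "lowestI")
  e <- edges(net)
  # triplet 2 (I = 0.1) wins: B->T cooperative, A-|T competitive
  expect_identical(e$sign[e$source == "B"], "cooperative")
  expect_identical(e$sign[e$source == "A"], "competitive")
  expect_equal(nrow(e), 2)
})

test_that("topK caps the triplets entering the network", {
  tr <- rankTriplets(data.frame(m = c("A", "C"), c = c("B", "D"), t = "T",
                                L = c(0.1, 0.2), Ld = 0.1, D = 0, I = c(0.1, 0.2)))
  net <- buildNetwork(tr, topK = 1)
  expect_equal(nrow(edges(net)), 2)
  expect_setequal(nodes(net), c("A", "B", "T"))
})

test_that("edge and node counts are bounded by the retained triplets", {
  set.seed(84)
  tr <- scanTriplets(rand_srp(6, 8))
  kept <- filterTriplets(tr, 3.8, 3.8)
  if (nrow(kept)) {
    net <- buildNetwork(rankTriplets(kept), conflict = "lowestI")
    expect_lte(nrow(edges(net)), 2 * nrow(kept))
    expect_lte(length(nodes(net)), 3 * nrow(kept))
  }
})
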