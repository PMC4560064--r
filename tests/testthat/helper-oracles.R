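# Independent brute-force oracles. These re-derive every score from the
# written formulas with scalar arithmetic and explicit loops; they share no
# code with the package internals.

oracle_surface <- function(x, y) {
  stopifnot(x >= 0, x <= 1, y >= 0, y <= 1)
  v <- if (x >= 0 && x < 0.5 && y > 0.5 && y <= 1) {
    2 * tanh(1.1 * x) * (1 - tanh(1.1 * y))
  } else if (x > 0.5 && x <= 1 && y >= 0 && y < 0.5) {
    1 - 2 * (1 - tanh(1.1 * x)) * tanh(1.1 * y)
  } else {
    tanh(1.1 * x) - tanh(1.1 * y) + 0.5
  }
  min(max(v, 0), 1)
}

oracle_lack_of_fit <- function(m, c, t) {
  num <- 0
  den <- 0
  tbar <- sum(t) / length(t)
  for (i in seq_along(t)) {
    num <- num + (t[i] - oracle_surface(m[i], c[i]))^2
    den <- den + (t[i] - tbar)^2
  }
  num / den
}

# naive deletion oracle: lack-of-fit recomputed on the k-1 remaining points
oracle_loo_refit <- function(m, c, t) {
  vapply(seq_along(t), function(i)
    oracle_lack_of_fit(m[-i], c[-i], t[-i]), numeric(1))
}

# anchored oracle: drop the point from the residual sum only
oracle_loo_anchored <- function(m, c, t) {
  tbar <- mean(t)
  den <- sum((t - tbar)^2)
  vapply(seq_along(t), function(i) {
    num <- 0
    for (j in seq_along(t)[-i])
      num <- num + (t[j] - oracle_surface(m[j], c[j]))^2
    num / den
  }, numeric(1))
}

oracle_adjustment <- function(L, loo) {
  total <- 0
  for (x in loo) {
    r <- x / L
    if (r > 0) total <- total + abs(r * log10(r))
  }
  total
}

# rank-and-Pearson oracle for Spearman
oracle_spearman <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# three-nested-loop triplet scan
oracle_scan <- function(P, scheme = "anchored") {
  n <- nrow(P)
  rows <- list()
  for (m in 1:n) for (c in 1:n) for (t in 1:n) {
    if (m == c || m == t || c == t) next
    L <- oracle_lack_of_fit(P[m, ], P[c, ], P[t, ])
    loo <- if (scheme == "anchored") oracle_loo_anchored(P[m, ], P[c, ], P[t, ])
           else oracle_loo_refit(P[m, ], P[c, ], P[t, ])
    D <- if (L == 0) 0 else oracle_adjustment(L, loo)
    rows[[length(rows) + 1L]] <- data.frame(
      mIdx = m, cIdx = c, tIdx = t, L = L, D = D, I = L * (1 + D),
      Ld = if (L >= 1) Inf else L / (1 - L))
  }
  do.call(rbind, rows)
}

# random SRP matrix: uniform rows min-max scaled to span [0, 1]
rand_srp <- function(n, k) {
  P <- matrix(runif(n * k), n, k)
  t(apply(P, 1L, function(r) (r - min(r)) / (max(r) - min(r))))
}

# random SRP series triple for score tests
rand_series <- function(k) {
  t <- runif(k)
  while (diff(range(t)) == 0) t <- runif(k)
  list(m = runif(k), c = runif(k), t = t)
}
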