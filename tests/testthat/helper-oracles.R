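# Independent oracles kept deliberately naive: term-by-term pmf sums and
# exhaustive searches, no shared code with the package internals.

# literal term-by-term binomial pmf summation
oracle_binom_cdf <- function(q, n, p) {
  if (q < 0) return(0)
  k <- 0:min(q, n)
  sum(choose(n, k) * p^k * (1 - p)^(n - k))
}

oracle_errors <- function(n, d, pU, pL) {
  c(alpha = oracle_binom_cdf(d - 1, n, pU),
    beta = 1 - oracle_binom_cdf(d - 1, n, pL))
}

# exhaustive minimax search over d = 0..n
oracle_minimax_d <- function(n, pU, pL) {
  best_d <- NA_integer_; best <- Inf
  for (d in 0:n) {
    e <- oracle_errors(n, d, pU, pL)
    if (max(e) < best - 1e-15) { best <- max(e); best_d <- d }
  }
  best_d
}

# exact distribution of the reflected random walk, by chain enumeration
oracle_walk_dist <- function(n, p, K = 2000) {
  probs <- numeric(n)
  g <- stats::dgeom(0:K, p)
  g[K + 1] <- g[K + 1] + stats::pgeom(K, p, lower.tail = FALSE)
  for (e in 1:n) for (dir in c(-1, 1)) for (s in 0:K) {
    pos <- e + dir * s
    while (pos < 1 || pos > n) {
      if (pos < 1) pos <- 2 - pos
      if (pos > n) pos <- 2 * n - pos
    }
    probs[pos] <- probs[pos] + (1 / n) * 0.5 * g[s + 1]
  }
  probs
}

batil_fit <- function() {
  bp <- batil_preset()
  lqas(bp$counts, bp$indicators)
}
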