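# Independent oracles, deliberately implemented by different routes than the
# package functions they cross-check.

# ROC AUC by explicit enumeration of all (disease, healthy) pairs.
brute_force_auc <- function(disease, healthy) {
  wins <- 0
  for (d in disease) for (h in healthy)
    wins <- wins + if (d > h) 1 else if (d == h) 0.5 else 0
  wins / (length(disease) * length(healthy))
}

# Signed KS statistic via a cumulative walk down the ranking: at every tag
# position record the two one-sided deviations of the tag ECDF from the
# uniform position fraction.
walk_ks <- function(ranked, tags) {
  n <- length(ranked)
  t <- length(tags)
  hits <- 0
  a <- -Inf
  b <- -Inf
  for (i in seq_len(n)) {
    if (ranked[i] %in% tags) {
      hits <- hits + 1
      a <- max(a, hits / t - i / n)
      b <- max(b, i / n - (hits - 1) / t)
    }
  }
  if (a > b) a else if (b > a) -b else 0
}

# Exact two-sided tail probability of |Z| >= z for N equiprobable +/-1 gene
# states, by direct enumeration over the number of consistent genes.
exact_z_tail <- function(n, z = 2) {
  k <- 0:n
  zs <- abs(2 * k - n) / sqrt(n)
  sum(stats::dbinom(k[zs >= z], n, 0.5))
}
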