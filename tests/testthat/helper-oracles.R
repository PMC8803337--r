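# Independent oracles and small fixture builders. Each oracle recomputes a
# statistic from first principles (enumeration, closed form, or a different
# library route) so implementation and check never share code.

# BH step-up computed literally from the definition.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- p[ord] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) q[i] <- min(q[i], q[i + 1])
  pmin(q, 1)[order(ord)]
}

# Spearman as Pearson of midranks, written out.
oracle_spearman <- function(a, b) {
  ra <- rank(a)
  rb <- rank(b)
  sum((ra - mean(ra)) * (rb - mean(rb))) /
    sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
}

# Hypergeometric upper tail P(X >= obs) by combinatorial summation.
oracle_hyper_tail <- function(obs, N, K, n) {
  js <- seq(obs, min(n, K))
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Same tail by exhaustively enumerating every possible query draw of size n
# from a universe of size N with K marked genes (feasible for small N).
oracle_hyper_enum <- function(obs, N, K, n) {
  draws <- combn(N, n)
  hits <- colSums(draws <= K)   # genes 1..K are the marked ones
  mean(hits >= obs)
}

# Exact rank-sum tail by enumerating all placements of k member positions
# among n ranks. Returns P(sum of member positions <= s) and >= s.
oracle_ranksum_enum <- function(positions, n) {
  k <- length(positions)
  s <- sum(positions)
  all_sums <- combn(n, k, sum)
  list(p_low = mean(all_sums <= s), p_high = mean(all_sums >= s))
}

# Overlap-curve area evaluated step by step from its definition.
oracle_area <- function(ref_genes, query) {
  n <- length(ref_genes)
  k <- sum(ref_genes %in% query)
  total <- 0
  c_i <- 0
  for (i in seq_len(n)) {
    if (ref_genes[i] %in% query) c_i <- c_i + 1
    total <- total + (c_i / k - i / n)
  }
  total / n
}

# Minimal de_table from named fold changes (p/fdr filled as given).
toy_table <- function(fc, p = NULL, fdr = NULL, label = "toy",
                      species = "synthetic") {
  if (is.null(p)) p <- rep(0.5, length(fc))
  de_table(names(fc), unname(fc), p, fdr = fdr, label = label,
           species = species)
}

# Write a DE table fixture file; returns the path.
write_de_fixture <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# The canonical small config used across planted-truth tests: the package's
# default study conditions with a caller-chosen seed.
study_config <- function(seed) generative_config(seed = seed)
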