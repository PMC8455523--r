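# Independent oracles the vectorized implementations are checked against.

# Connectivity by explicit double loop over gene pairs.
naive_connectivity <- function(cor_matrix, beta = 5) {
  g <- nrow(cor_matrix)
  k <- numeric(g)
  for (i in seq_len(g)) {
    for (j in seq_len(g)) {
      if (i != j) k[i] <- k[i] + abs(cor_matrix[i, j])^beta
    }
  }
  k
}

# Hypergeometric upper tail P(X >= k) by direct combinatorial summation.
hyper_tail_oracle <- function(k, m, N, q) {
  hi <- min(m, q)
  if (k > hi) return(0)
  i <- max(k, 0):hi
  sum(choose(m, i) * choose(N - m, q - i)) / choose(N, q)
}

# Upper-tail overlap p by exhaustive enumeration of all size-q draws from the
# pool (the add-one-corrected Monte-Carlo estimator converges to a value
# between this exact tail probability and itself plus the point mass).
exact_overlap_tail <- function(query, target, pool, observed) {
  q <- length(query)
  draws <- utils::combn(pool, q, simplify = FALSE)
  mean(vapply(draws, function(d) length(intersect(d, target)) >= observed,
              logical(1)))
}

# Random correlation matrix derived from actual data, so it is exactly
# symmetric with unit diagonal.
random_cor_matrix <- function(n_genes, n_samples) {
  stats::cor(matrix(stats::rnorm(n_genes * n_samples), ncol = n_genes))
}
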