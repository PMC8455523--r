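# The co-expression quantity the gradient sweep tracks: Pearson correlation,
# soft-threshold adjacency a_ij = |r_ij|^beta (beta = 5), and whole-network
# connectivity k_i = sum_{j != i} a_ij.

#' Gene-gene Pearson correlation matrix
#'
#' Correlations are computed across samples on log2 expression values. A gene
#' with zero variance in the given subset has its correlations set to 0 (not
#' NaN), with a warning, so downstream adjacency sums stay finite.
#'
#' @param log_expr genes x samples matrix of log2 expression values.
#' @return symmetric genes x genes correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(log_expr) {
  log_expr <- as.matrix(log_expr)
  if (ncol(log_expr) < 3) stop("need at least 3 samples for correlation", call. = FALSE)
  zero_var <- apply(log_expr, 1, stats::sd) == 0
  r <- suppressWarnings(stats::cor(t(log_expr)))
  if (any(zero_var)) {
    warning(sprintf("%d zero-variance gene(s): correlations set to 0", sum(zero_var)))
    r[zero_var, ] <- 0
    r[, zero_var] <- 0
    diag(r) <- 1
  }
  r
}

#' Soft-threshold adjacency
#'
#' Unsigned WGCNA-style adjacency `a_ij = |r_ij|^beta`; with `signed = TRUE`,
#' `a_ij = ((1 + r_ij) / 2)^beta`. The diagonal is set to 0 so connectivity
#' excludes self-adjacency.
#'
#' @param cor_matrix symmetric correlation matrix.
#' @param beta positive soft-threshold exponent (default 5).
#' @param signed use the signed transform instead of absolute correlation.
#' @return adjacency matrix with entries in `[0, 1]` and zero diagonal.
#' @export
soft_threshold_adjacency <- function(cor_matrix, beta = 5, signed = FALSE) {
  if (!is.numeric(beta) || beta <= 0) stop("'beta' must be > 0", call. = FALSE)
  a <- if (signed) ((1 + cor_matrix) / 2)^beta else abs(cor_matrix)^beta
  diag(a) <- 0
  a
}

#' Per-gene whole-network connectivity
#'
#' `k_i = sum_j a_ij`, the gene's total co-expression strength. With a zero
#' diagonal this equals the sum over the other genes, bounded by `n_genes - 1`.
#'
#' @param adjacency square symmetric adjacency matrix with zero diagonal.
#' @return named numeric vector of connectivities.
#' @export
connectivity <- function(adjacency) {
  adjacency <- as.matrix(adjacency)
  if (nrow(adjacency) != ncol(adjacency) ||
      !isSymmetric(unname(adjacency), tol = 1e-8)) {
    stop("adjacency must be square and symmetric", call. = FALSE)
  }
  if (any(abs(diag(adjacency)) > 1e-12)) {
    stop("adjacency diagonal must be zero (self-adjacency excluded)", call. = FALSE)
  }
  rowSums(adjacency)
}

# Connectivity of every gene within one sample subset: the composed
# correlation -> adjacency -> row-sum step used at each sweep population.
population_connectivity <- function(log_expr, sample_ids, beta = 5,
                                    signed = FALSE) {
  r <- correlation_matrix(log_expr[, sample_ids, drop = FALSE])
  connectivity(soft_threshold_adjacency(r, beta = beta, signed = signed))
}
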