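# Sample, tissue, and gene selection for TPM expression data, plus the
# log2(TPM + 1) transform and a PCA quality check on the most variable genes.

#' Retain samples passing the RNA-quality (RIN) filter
#'
#' Samples are kept when their RNA integrity number is strictly greater than
#' `rin_min` (a sample at exactly the threshold is excluded). Samples with a
#' missing RIN are excluded with a warning.
#'
#' @param metadata data.frame with at least `sample_id` and `rin` columns.
#' @param rin_min strict lower bound on RIN (default 6.0).
#' @return character vector of retained sample IDs, input order preserved.
#' @export
filter_samples <- function(metadata, rin_min = 6.0) {
  stopifnot(is.data.frame(metadata))
  if (!nrow(metadata)) return(character(0))
  if (!"rin" %in% names(metadata)) stop("metadata lacks a 'rin' column", call. = FALSE)
  missing_rin <- is.na(metadata$rin)
  if (any(missing_rin)) {
    warning(sprintf("%d sample(s) with missing RIN excluded", sum(missing_rin)))
  }
  keep <- !missing_rin & metadata$rin > rin_min
  as.character(metadata$sample_id[keep])
}

#' Retain tissues with enough samples of both sexes
#'
#' A tissue qualifies when it has at least `min_samples_per_sex` female and at
#' least `min_samples_per_sex` male samples (inclusive bound). Apply after
#' [filter_samples()] so the counts reflect quality-passing samples.
#'
#' @param metadata data.frame with `tissue` and `sex` columns.
#' @param min_samples_per_sex inclusive per-sex minimum (default 80).
#' @return character vector of retained tissue labels.
#' @export
select_tissues <- function(metadata, min_samples_per_sex = 80) {
  stopifnot(is.data.frame(metadata),
            all(c("tissue", "sex") %in% names(metadata)))
  if (!nrow(metadata)) {
    warning("no tissues qualify")
    return(character(0))
  }
  tab <- table(metadata$tissue, metadata$sex)
  n_f <- if ("female" %in% colnames(tab)) tab[, "female"] else rep(0, nrow(tab))
  n_m <- if ("male" %in% colnames(tab)) tab[, "male"] else rep(0, nrow(tab))
  keep <- n_f >= min_samples_per_sex & n_m >= min_samples_per_sex
  out <- rownames(tab)[keep]
  if (!length(out)) warning("no tissues qualify")
  out
}

#' Log-transform a TPM matrix
#'
#' @param expr non-negative genes x samples TPM matrix.
#' @param pseudocount added before taking log2 (default 1, so TPM 0 maps to 0).
#' @return matrix of `log2(TPM + pseudocount)`, same shape and dimnames.
#' @export
log_transform <- function(expr, pseudocount = 1) {
  expr <- as.matrix(expr)
  if (any(expr < 0, na.rm = TRUE)) stop("expression values must be >= 0", call. = FALSE)
  if (pseudocount <= 0) stop("'pseudocount' must be > 0", call. = FALSE)
  log2(expr + pseudocount)
}

#' Select genes by mean expression and variance on the log2 scale
#'
#' A gene is retained when, over samples, the mean of `log2(TPM + pseudocount)`
#' is at least `mean_log2_tpm_min` and its unbiased (n-1 denominator) variance
#' is at least `var_log2_min`. Both filters act on the same log2 scale the
#' downstream correlation analysis uses.
#'
#' @param expr non-negative genes x samples TPM matrix with rownames.
#' @param mean_log2_tpm_min inclusive mean cut-off (default 1).
#' @param var_log2_min inclusive variance cut-off (default 1).
#' @param pseudocount see [log_transform()].
#' @return character vector of retained gene IDs.
#' @export
select_genes <- function(expr, mean_log2_tpm_min = 1, var_log2_min = 1,
                         pseudocount = 1) {
  expr <- as.matrix(expr)
  if (!nrow(expr)) stop("empty expression matrix", call. = FALSE)
  if (ncol(expr) < 2) stop("variance undefined with fewer than 2 samples", call. = FALSE)
  l <- log_transform(expr, pseudocount)
  mu <- rowMeans(l)
  v <- apply(l, 1, stats::var)
  rownames(expr)[mu >= mean_log2_tpm_min & v >= var_log2_min]
}

#' PCA quality check on the most variable genes
#'
#' Ranks genes by variance of their log2 values, keeps the top `n_top_genes`
#' (default 1000, capped at the gene count), and computes principal components
#' on the centered log2 matrix. Intended for visual QC of sample structure
#' (e.g. sex separation), not for any downstream statistic.
#'
#' @param expr non-negative genes x samples TPM matrix.
#' @param n_top_genes number of most-variable genes to use.
#' @param pseudocount see [log_transform()].
#' @return list with `scores` (data.frame: sample_id, PC1, PC2) and
#'   `var_explained` (length-2 numeric, fractions for PC1/PC2).
#' @export
pca_qc <- function(expr, n_top_genes = 1000, pseudocount = 1) {
  expr <- as.matrix(expr)
  if (ncol(expr) < 3) stop("PCA QC needs at least 3 samples", call. = FALSE)
  l <- log_transform(expr, pseudocount)
  v <- apply(l, 1, stats::var)
  if (all(v == 0)) stop("constant expression matrix: zero variance everywhere", call. = FALSE)
  if (n_top_genes > nrow(l)) {
    message(sprintf("n_top_genes (%d) exceeds gene count (%d); using all genes",
                    n_top_genes, nrow(l)))
    n_top_genes <- nrow(l)
  }
  keep <- order(v, decreasing = TRUE)[seq_len(n_top_genes)]
  if (length(keep) < 2) stop("fewer than 2 genes available for PCA", call. = FALSE)
  p <- stats::prcomp(t(l[keep, , drop = FALSE]), center = TRUE, scale. = FALSE)
  ve <- p$sdev^2 / sum(p$sdev^2)
  list(
    scores = data.frame(sample_id = colnames(expr),
                        PC1 = p$x[, 1],
                        PC2 = if (ncol(p$x) >= 2) p$x[, 2] else 0,
                        row.names = NULL, stringsAsFactors = FALSE),
    var_explained = ve[seq_len(min(2, length(ve)))]
  )
}
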