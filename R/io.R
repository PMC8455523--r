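# Plain-text readers and writers: TSV expression matrices and metadata,
# JSON planted truth, TSV bias-call tables.

#' Write / read a genes x samples expression matrix as TSV
#'
#' First column `gene_id`, remaining columns one per sample (header row of
#' sample IDs).
#'
#' @param expr genes x samples matrix with dimnames.
#' @param path file path.
#' @return `read_expression_tsv` returns the numeric matrix with dimnames.
#' @export
write_expression_tsv <- function(expr, path) {
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write / read sample metadata as TSV
#'
#' @param metadata data.frame (sample_id, sex, age_decade, rin, tissue).
#' @param path file path.
#' @export
write_metadata_tsv <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_metadata_tsv
#' @export
read_metadata_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Write / read planted synthetic truth as JSON
#'
#' @param truth the `truth` component of [generate_dataset()] output.
#' @param path file path.
#' @export
write_truth_json <- function(truth, path) {
  stopifnot(inherits(truth, "synthetic_truth"))
  jsonlite::write_json(list(genes = truth$genes, modules = truth$modules),
                       path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$genes$module <- as.character(x$genes$module)
  structure(list(genes = x$genes, modules = x$modules),
            class = "synthetic_truth")
}

#' Write a bias-call table as TSV
#'
#' @param bias_calls a `bias_call_table` from [run_consistency()].
#' @param path file path.
#' @export
write_bias_calls_tsv <- function(bias_calls, path) {
  utils::write.table(as.data.frame(bias_calls), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
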