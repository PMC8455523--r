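# Exact hypergeometric over-representation analysis against named gene-set
# collections (GMT), and evidence-score filtering of gene-disease association
# tables.

#' Construct a gene-set collection
#'
#' @param sets named list of character vectors of gene IDs; duplicate members
#'   within a set are removed.
#' @param universe optional character vector of all testable genes; defaults
#'   to the union of set members.
#' @return a `gene_set_collection` list with `sets` and `universe`.
#' @export
gene_set_collection <- function(sets, universe = NULL) {
  stopifnot(is.list(sets))
  if (length(sets) && (is.null(names(sets)) || any(names(sets) == ""))) {
    stop("every gene set must be named", call. = FALSE)
  }
  sets <- lapply(sets, function(s) unique(as.character(s)))
  universe <- unique(as.character(universe %||% unlist(sets, use.names = FALSE)))
  structure(list(sets = sets, universe = universe),
            class = "gene_set_collection")
}

#' Read a GMT gene-set file
#'
#' Standard GMT dialect: one set per non-empty line, tab-separated fields
#' `name`, `description`, then members. Duplicate members within a set are
#' dropped.
#'
#' @param path path to a GMT file.
#' @return a [gene_set_collection()]; set descriptions are kept in
#'   `attr(, "descriptions")`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  sets <- list()
  desc <- character(0)
  for (i in keep) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop(sprintf("malformed GMT line %d: fewer than 3 tab-separated fields", i),
           call. = FALSE)
    }
    sets[[fields[1]]] <- unique(fields[-(1:2)])
    desc[fields[1]] <- fields[2]
  }
  out <- gene_set_collection(sets)
  attr(out, "descriptions") <- desc
  out
}

#' Write a gene-set collection as GMT
#'
#' @param collection a [gene_set_collection()].
#' @param path output path.
#' @param descriptions optional named character vector of set descriptions;
#'   defaults to the set name.
#' @export
write_gmt <- function(collection, path, descriptions = NULL) {
  stopifnot(inherits(collection, "gene_set_collection"))
  descriptions <- descriptions %||% attr(collection, "descriptions")
  lines <- vapply(names(collection$sets), function(nm) {
    d <- if (!is.null(descriptions) && nm %in% names(descriptions)) {
      descriptions[[nm]]
    } else nm
    paste(c(nm, d, collection$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Over-representation analysis (exact hypergeometric)
#'
#' For each set, the upper-tail probability of observing at least the seen
#' overlap between the query and the set within the universe:
#' `p = P(X >= k)` with `X ~ Hypergeometric(m, N - m, q)` where `k` is the
#' overlap, `m` the in-universe set size, `q` the in-universe query size and
#' `N` the universe size. Query genes outside the universe are dropped with a
#' warning; set members outside the universe are ignored. No multiple-testing
#' correction enters the `significant` flag (raw `p < p_cutoff`); a
#' Benjamini-Hochberg column is provided alongside.
#'
#' @param query character vector of query gene IDs.
#' @param collection a [gene_set_collection()].
#' @param universe character vector of all testable genes; defaults to the
#'   collection's universe.
#' @param p_cutoff significance cut-off on the raw p-value (default 0.05).
#' @return data.frame sorted by ascending p-value with columns `term`,
#'   `overlap`, `query_size`, `set_size`, `universe_size`, `gene_ratio`,
#'   `p_value`, `p_adjust`, `significant`, `genes` (comma-separated overlap).
#' @export
ora <- function(query, collection, universe = NULL, p_cutoff = 0.05) {
  stopifnot(inherits(collection, "gene_set_collection"))
  universe <- unique(as.character(universe %||% collection$universe))
  if (!length(universe)) stop("empty universe", call. = FALSE)
  query <- unique(as.character(query))
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(sprintf("%d query gene(s) outside the universe dropped", length(outside)))
    query <- intersect(query, universe)
  }
  empty <- data.frame(term = character(0), overlap = integer(0),
                      query_size = integer(0), set_size = integer(0),
                      universe_size = integer(0), gene_ratio = numeric(0),
                      p_value = numeric(0), p_adjust = numeric(0),
                      significant = logical(0), genes = character(0),
                      stringsAsFactors = FALSE)
  if (!length(query)) {
    warning("query empty after intersecting with the universe")
    return(empty)
  }
  n_univ <- length(universe)
  q <- length(query)
  rows <- lapply(names(collection$sets), function(nm) {
    members <- intersect(collection$sets[[nm]], universe)
    m <- length(members)
    hit <- intersect(members, query)
    k <- length(hit)
    p <- stats::phyper(k - 1, m, n_univ - m, q, lower.tail = FALSE)
    data.frame(term = nm, overlap = k, query_size = q, set_size = m,
               universe_size = n_univ, gene_ratio = k / q, p_value = p,
               genes = paste(hit, collapse = ","), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjust <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- out$p_value < p_cutoff
  out <- out[order(out$p_value), c("term", "overlap", "query_size", "set_size",
                                   "universe_size", "gene_ratio", "p_value",
                                   "p_adjust", "significant", "genes")]
  rownames(out) <- NULL
  out
}

#' Run ORA for several query sets against a shared universe
#'
#' @param queries named list of query gene-ID vectors (e.g. female-biased,
#'   male-biased, tissue-specific subsets).
#' @inheritParams ora
#' @return long-format data.frame: the [ora()] output of every query stacked,
#'   keyed by a leading `query_set` column.
#' @export
compare_clusters <- function(queries, collection, universe = NULL,
                             p_cutoff = 0.05) {
  stopifnot(is.list(queries), !is.null(names(queries)), all(nzchar(names(queries))))
  out <- lapply(names(queries), function(nm) {
    res <- ora(queries[[nm]], collection, universe = universe,
               p_cutoff = p_cutoff)
    if (nrow(res)) cbind(query_set = nm, res, stringsAsFactors = FALSE) else NULL
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(query_set = character(0), term = character(0))
  }
  rownames(out) <- NULL
  out
}

#' Per-term significance codes across two query sets
#'
#' Collapses a [compare_clusters()] table into the code used for
#' significance heatmaps: for each term, whether it is significant in the
#' first query set only, the second only, `both`, or `none`.
#'
#' @param cc a [compare_clusters()] result.
#' @param set_names length-2 character vector naming the two query sets
#'   (default `c("female", "male")`).
#' @return data.frame with columns `term` and `code`.
#' @export
significance_codes <- function(cc, set_names = c("female", "male")) {
  stopifnot(length(set_names) == 2, all(set_names %in% cc$query_set))
  terms <- unique(cc$term)
  sig_in <- function(set) {
    terms %in% cc$term[cc$query_set == set & cc$significant]
  }
  a <- sig_in(set_names[1])
  b <- sig_in(set_names[2])
  code <- rep("none", length(terms))
  code[a & !b] <- set_names[1]
  code[b & !a] <- set_names[2]
  code[a & b] <- "both"
  data.frame(term = terms, code = code, stringsAsFactors = FALSE)
}

#' Filter a gene-disease association table
#'
#' Two sequential steps: (1) keep diseases with at least
#' `min_genes_per_disease` annotated genes; (2) over the surviving rows, keep
#' associations whose evidence score is at least the `score_quantile` quantile
#' (linear-interpolation estimator) of the surviving scores.
#'
#' @param associations data.frame with columns `gene`, `disease`, `score`.
#' @param min_genes_per_disease inclusive per-disease gene minimum (default 100).
#' @param score_quantile quantile level for the score cut (default 0.90).
#' @return the filtered data.frame; the score threshold used is attached as
#'   `attr(, "score_threshold")`.
#' @export
filter_associations <- function(associations, min_genes_per_disease = 100,
                                score_quantile = 0.90) {
  stopifnot(is.data.frame(associations))
  if (!nrow(associations)) return(associations)
  stopifnot(all(c("gene", "disease", "score") %in% names(associations)),
            is.numeric(associations$score))
  if (score_quantile <= 0 || score_quantile >= 1) {
    stop("'score_quantile' must lie in (0, 1)", call. = FALSE)
  }
  n_genes <- tapply(associations$gene, associations$disease,
                    function(g) length(unique(g)))
  keep_dis <- names(n_genes)[n_genes >= min_genes_per_disease]
  step1 <- associations[associations$disease %in% keep_dis, , drop = FALSE]
  if (!nrow(step1)) {
    attr(step1, "score_threshold") <- NA_real_
    return(step1)
  }
  thr <- stats::quantile(step1$score, score_quantile, names = FALSE, type = 7)
  out <- step1[step1$score >= thr, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "score_threshold") <- thr
  out
}
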