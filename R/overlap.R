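# Set-overlap permutation tests (sex-biased genes vs disease genes or drug
# targets) and the differential-expression vs co-expression-bias overlap
# report.

#' Permutation test for the overlap of two gene sets
#'
#' Draws `n_perm` size-matched random subsets of `permutation_pool` (without
#' replacement within each draw) and records their overlap with `target_set`.
#' The headline p-value is the upper tail with add-one correction,
#' `p = (1 + #{null >= observed}) / (n_perm + 1)`, so its floor is
#' `1/(n_perm + 1)`. The proportion of null overlaps strictly below the
#' observed one is also reported as a diagnostic (`prop_lower`).
#'
#' @param query_set gene IDs whose overlap with the target is being tested
#'   (e.g. sex-biased disease genes).
#' @param target_set gene IDs of the reference set (e.g. FDA-approved drug
#'   targets).
#' @param permutation_pool gene IDs the null subsets are drawn from (e.g.
#'   non-sex-biased analyzed genes); genes shared with the query are removed
#'   with a warning.
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed.
#' @return an `overlap_permutation` list: `observed_overlap`, `null_overlaps`,
#'   `p_value`, `prop_lower`, `n_perm`, `seed`.
#' @export
overlap_permutation_test <- function(query_set, target_set, permutation_pool,
                                     n_perm = 10000, seed = 1) {
  query <- unique(as.character(query_set))
  target <- unique(as.character(target_set))
  pool <- unique(as.character(permutation_pool))
  shared <- intersect(query, pool)
  if (length(shared)) {
    warning(sprintf("%d gene(s) shared between query and pool removed from pool",
                    length(shared)))
    pool <- setdiff(pool, query)
  }
  q <- length(query)
  if (length(pool) < q) {
    stop(sprintf("permutation pool (%d) smaller than query (%d)",
                 length(pool), q), call. = FALSE)
  }
  n_perm <- check_count(n_perm, "n_perm", min = 1)
  observed <- length(intersect(query, target))
  in_target <- pool %in% target
  set.seed(seed)
  null_overlaps <- vapply(seq_len(n_perm), function(i) {
    sum(in_target[sample.int(length(pool), q)])
  }, integer(1))
  structure(list(
    observed_overlap = observed,
    null_overlaps = null_overlaps,
    p_value = (1 + sum(null_overlaps >= observed)) / (n_perm + 1),
    prop_lower = mean(null_overlaps < observed),
    n_perm = n_perm,
    seed = as.integer(seed)
  ), class = "overlap_permutation")
}

#' @export
print.overlap_permutation <- function(x, ...) {
  cat(sprintf(
    "Overlap permutation test: observed %d, null mean %.2f (%d perms), p = %.4g\n",
    x$observed_overlap, mean(x$null_overlaps), x$n_perm, x$p_value))
  invisible(x)
}

#' Overlap between differential expression and co-expression bias
#'
#' Compares, per sex, an externally produced list of differentially expressed
#' genes (higher expressed in that sex) with the co-expression-biased genes
#' of the same sex: overlap count, Jaccard index, and the fraction of each
#' list covered.
#'
#' @param de_up_in_females,de_up_in_males differential-expression gene lists.
#' @param female_biased,male_biased co-expression-biased gene lists.
#' @return data.frame with one row per sex: `sex`, `n_de`, `n_biased`,
#'   `overlap`, `jaccard`, `frac_of_de`, `frac_of_biased`.
#' @export
de_bias_overlap <- function(de_up_in_females, de_up_in_males,
                            female_biased, male_biased) {
  one <- function(sex, de, biased) {
    de <- unique(as.character(de)); biased <- unique(as.character(biased))
    k <- length(intersect(de, biased))
    u <- length(union(de, biased))
    data.frame(sex = sex, n_de = length(de), n_biased = length(biased),
               overlap = k,
               jaccard = if (u > 0) k / u else 0,
               frac_of_de = if (length(de)) k / length(de) else 0,
               frac_of_biased = if (length(biased)) k / length(biased) else 0,
               stringsAsFactors = FALSE)
  }
  rbind(one("female", de_up_in_females, female_biased),
        one("male", de_up_in_males, male_biased))
}
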