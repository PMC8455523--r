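# The core procedure: sweep connectivity across n+1 equal-size populations
# shifting one sample at a time from all-group1 (female) to all-group2 (male),
# quintilize each gene's trajectory, threshold the log2-fold change between
# the extreme quintiles, repeat with fresh random samples, and require calls
# to be consistent across iterations. A random-population permutation null
# calibrates the count of threshold-passing genes, and the menopause variant
# runs the same machinery within females over an age-50 dichotomy.

#' Configure the gradient sweep
#'
#' @param population_size population size n at every sweep step; defaults to
#'   the smaller sex's sample count at run time, so both extremes of the
#'   gradient are equally powered.
#' @param n_iterations number of repeated randomized sweeps (default 100).
#' @param log2fc_threshold per-iteration call threshold on the extreme-quintile
#'   log2-fold change; strict (a gene at exactly the threshold is not called).
#' @param min_calls inclusive minimum number of calling iterations for the
#'   final sex-biased label (default 20).
#' @param epsilon pseudo-connectivity added inside the log2 ratio to guard
#'   zero medians; far below any connectivity of a correlated gene.
#' @param beta,signed soft-threshold adjacency parameters, see
#'   [soft_threshold_adjacency()].
#' @param seed master seed; per-iteration child seeds are derived from it.
#' @return a `sweep_config` list.
#' @export
sweep_config <- function(population_size = NULL, n_iterations = 100,
                         log2fc_threshold = 1, min_calls = 20,
                         epsilon = 1e-6, beta = 5, signed = FALSE, seed = 1) {
  n_iterations <- check_count(n_iterations, "n_iterations", min = 1)
  min_calls <- check_count(min_calls, "min_calls", min = 1)
  if (min_calls > n_iterations) {
    stop("'min_calls' cannot exceed 'n_iterations'", call. = FALSE)
  }
  if (!is.numeric(log2fc_threshold) || log2fc_threshold <= 0) {
    stop("'log2fc_threshold' must be > 0", call. = FALSE)
  }
  if (!is.null(population_size)) {
    population_size <- check_count(population_size, "population_size", min = 3)
  }
  structure(list(population_size = population_size,
                 n_iterations = n_iterations,
                 log2fc_threshold = log2fc_threshold,
                 min_calls = min_calls, epsilon = epsilon,
                 beta = beta, signed = signed, seed = as.integer(seed)),
            class = "sweep_config")
}

#' Build one female-to-male gradient plan
#'
#' Step 0 is a random subset of `population_size` females; at each subsequent
#' step one random remaining female is removed and one random unused male
#' (from a random male subset of the same size) is added, until step n is
#' all-male. Every population has exactly `population_size` members and
#' consecutive populations differ by one removal plus one addition.
#'
#' @param female_ids,male_ids sample ID pools for the two ends of the gradient.
#' @param population_size population size n (>= 3).
#' @param seed optional seed; `NULL` continues the current RNG stream.
#' @return list of n+1 character vectors of sample IDs (a `gradient_plan`).
#' @export
build_gradient_plan <- function(female_ids, male_ids, population_size,
                                seed = NULL) {
  population_size <- check_count(population_size, "population_size", min = 3)
  for (side in list(list(ids = female_ids, name = "female"),
                    list(ids = male_ids, name = "male"))) {
    if (length(side$ids) < population_size) {
      stop(sprintf("not enough %s samples: need %d, have %d",
                   side$name, population_size, length(side$ids)), call. = FALSE)
    }
  }
  if (!is.null(seed)) set.seed(seed)
  n <- population_size
  start <- sample(as.character(female_ids), n)       # step-0 females
  removal <- sample(start, n)                        # order females leave
  addition <- sample(as.character(male_ids), n)      # order males enter
  plan <- vector("list", n + 1L)
  plan[[1L]] <- start
  for (k in seq_len(n)) {
    plan[[k + 1L]] <- c(setdiff(plan[[k]], removal[k]), addition[k])
  }
  structure(plan, class = "gradient_plan")
}

#' Recompute connectivity along a gradient plan
#'
#' @param log_expr genes x samples log2 expression matrix containing every
#'   sample the plan names.
#' @param plan a [build_gradient_plan()] result (or any list of sample-ID
#'   vectors, each of size >= 3).
#' @param beta,signed adjacency parameters.
#' @return genes x (n+1) connectivity trajectory matrix.
#' @export
run_sweep <- function(log_expr, plan, beta = 5, signed = FALSE) {
  log_expr <- as.matrix(log_expr)
  all_ids <- unique(unlist(plan))
  missing <- setdiff(all_ids, colnames(log_expr))
  if (length(missing)) {
    stop(sprintf("plan samples absent from matrix: %s",
                 paste(utils::head(missing, 5), collapse = ", ")), call. = FALSE)
  }
  if (any(lengths(plan) < 3)) stop("every population needs >= 3 samples", call. = FALSE)
  traj <- vapply(plan, function(ids) {
    population_connectivity(log_expr, ids, beta = beta, signed = signed)
  }, numeric(nrow(log_expr)))
  rownames(traj) <- rownames(log_expr)
  traj
}

#' Quintilize a connectivity trajectory
#'
#' The n+1 ordered populations are assigned to five contiguous blocks by
#' `block(i) = floor(5 * i / (n + 1))` for `i = 0..n` (block sizes differ by
#' at most 1), and each gene is summarized by its median connectivity within
#' each block. Block 1 is the female-most fifth, block 5 the male-most.
#'
#' @param trajectory genes x (n+1) connectivity matrix from [run_sweep()].
#' @return genes x 5 matrix of per-block medians (columns Q1..Q5).
#' @export
quintilize <- function(trajectory) {
  trajectory <- as.matrix(trajectory)
  n1 <- ncol(trajectory)
  if (n1 < 5) stop("need at least 5 populations to quintilize", call. = FALSE)
  block <- floor(5 * (seq_len(n1) - 1) / n1)
  q <- vapply(0:4, function(b) {
    apply(trajectory[, block == b, drop = FALSE], 1, stats::median)
  }, numeric(nrow(trajectory)))
  q <- matrix(q, nrow = nrow(trajectory))
  dimnames(q) <- list(rownames(trajectory), paste0("Q", 1:5))
  q
}

#' Extreme-quintile log2-fold change
#'
#' `log2(Q5 + epsilon) - log2(Q1 + epsilon)`: positive values mean higher
#' connectivity in male-dominated populations (male-biased direction),
#' negative female-biased.
#'
#' @param quintiles genes x 5 matrix from [quintilize()].
#' @param epsilon pseudo-connectivity guarding zero medians.
#' @return named numeric vector of per-gene log2-fold changes.
#' @export
log2_shift <- function(quintiles, epsilon = 1e-6) {
  quintiles <- as.matrix(quintiles)
  stopifnot(ncol(quintiles) == 5)
  out <- log2(quintiles[, 5] + epsilon) - log2(quintiles[, 1] + epsilon)
  names(out) <- rownames(quintiles)
  out
}

#' Call one sweep iteration
#'
#' Strict threshold: `male` if log2fc > threshold, `female` if
#' log2fc < -threshold, otherwise `none`. A gene at exactly the threshold is
#' not called.
#'
#' @param log2fc per-gene log2-fold changes.
#' @param threshold positive call threshold (default 1).
#' @return character vector in `{"male", "female", "none"}`.
#' @export
call_iteration <- function(log2fc, threshold = 1) {
  stopifnot(all(is.finite(log2fc)))
  out <- ifelse(log2fc > threshold, "male",
                ifelse(log2fc < -threshold, "female", "none"))
  names(out) <- names(log2fc)
  out
}

# Shared engine for the sex sweep and the menopause variant: group1 occupies
# the gradient's start (negative log2fc direction), group2 its end (positive).
run_group_consistency <- function(log_expr, group1_ids, group2_ids, config,
                                  labels = c("female", "male")) {
  log_expr <- as.matrix(log_expr)
  n <- config$population_size %||% min(length(group1_ids), length(group2_ids))
  n <- check_count(n, "population_size", min = 3)
  for (side in list(list(ids = group1_ids, name = labels[1]),
                    list(ids = group2_ids, name = labels[2]))) {
    if (length(side$ids) < n) {
      stop(sprintf("not enough %s samples: need %d, have %d",
                   side$name, n, length(side$ids)), call. = FALSE)
    }
  }
  seeds <- derive_seeds(config$seed, config$n_iterations)
  n_g <- nrow(log_expr)
  lfc <- matrix(NA_real_, n_g, config$n_iterations,
                dimnames = list(rownames(log_expr), NULL))
  for (it in seq_len(config$n_iterations)) {
    plan <- build_gradient_plan(group1_ids, group2_ids, n, seed = seeds[it])
    traj <- run_sweep(log_expr, plan, beta = config$beta, signed = config$signed)
    lfc[, it] <- log2_shift(quintilize(traj), config$epsilon)
  }
  finalize_bias_calls(lfc, config, labels)
}

# Turn the per-iteration log2fc record into the final call table.
finalize_bias_calls <- function(lfc, config, labels = c("female", "male")) {
  thr <- config$log2fc_threshold
  up <- lfc > thr        # toward group2 (labels[2])
  down <- lfc < -thr     # toward group1 (labels[1])
  n_up <- rowSums(up)
  n_down <- rowSums(down)
  n_called <- n_up + n_down
  direction <- rep("none", nrow(lfc))
  direction[n_up > n_down] <- labels[2]
  direction[n_down > n_up] <- labels[1]
  tied <- n_called > 0 & n_up == n_down
  if (any(tied)) {
    warning(sprintf("%d gene(s) with tied call direction left as 'none'", sum(tied)))
  }
  out <- data.frame(
    gene_id = rownames(lfc),
    mean_log2fc = rowMeans(lfc),
    direction = direction,
    n_called = as.integer(n_called),
    is_sex_biased = n_called >= config$min_calls,
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(out, "log2fc") <- lfc
  attr(out, "iteration_counts") <- colSums(abs(lfc) > thr)
  attr(out, "labels") <- labels
  class(out) <- c("bias_call_table", "data.frame")
  out
}

#' Repeated randomized sweeps with the consistency filter
#'
#' Runs `n_iterations` independent gradient sweeps (fresh random subsample and
#' shift order each time, child seeds derived from `config$seed`), records
#' each gene's per-iteration extreme-quintile log2-fold change, and labels a
#' gene sex-biased when it is called in at least `min_calls` iterations.
#' Direction is the majority vote among calling iterations; ties are surfaced
#' with a warning and left as `none`.
#'
#' @param log_expr genes x samples log2 expression matrix.
#' @param metadata data.frame with `sample_id` and `sex` columns covering the
#'   matrix columns.
#' @param config a [sweep_config()].
#' @return a `bias_call_table` data.frame (gene_id, mean_log2fc, direction,
#'   n_called, is_sex_biased) carrying the full genes x iterations log2fc
#'   record in `attr(, "log2fc")` and the per-iteration count of
#'   threshold-passing genes in `attr(, "iteration_counts")`.
#' @export
run_consistency <- function(log_expr, metadata, config = sweep_config()) {
  stopifnot(is.data.frame(metadata),
            all(c("sample_id", "sex") %in% names(metadata)))
  ids <- intersect(metadata$sample_id, colnames(log_expr))
  md <- metadata[match(ids, metadata$sample_id), ]
  run_group_consistency(log_expr,
                        group1_ids = md$sample_id[md$sex == "female"],
                        group2_ids = md$sample_id[md$sex == "male"],
                        config = config,
                        labels = c("female", "male"))
}

#' Random-population permutation null
#'
#' Repeats the sweep machinery with populations of the same sizes but samples
#' drawn uniformly from the pooled sexes (no gradient), recording per
#' permutation the number of genes whose absolute extreme-quintile log2-fold
#' change passes the threshold. The 2.5th/97.5th percentiles of those counts
#' give the 95% null interval the gradient counts are compared against.
#'
#' @inheritParams run_consistency
#' @param n_permutations number of null permutations (default: the config's
#'   `n_iterations`).
#' @return list with `counts` (per-permutation threshold-passing gene counts),
#'   `lower`/`upper` (2.5/97.5 percentile bounds), `n_permutations`,
#'   `threshold`, and `population_size`.
#' @export
run_null <- function(log_expr, metadata, config = sweep_config(),
                     n_permutations = NULL) {
  stopifnot(is.data.frame(metadata),
            all(c("sample_id", "sex") %in% names(metadata)))
  n_permutations <- n_permutations %||% config$n_iterations
  ids <- intersect(metadata$sample_id, colnames(log_expr))
  md <- metadata[match(ids, metadata$sample_id), ]
  n <- config$population_size %||%
    min(sum(md$sex == "female"), sum(md$sex == "male"))
  n <- check_count(n, "population_size", min = 3)
  pool <- md$sample_id
  if (length(pool) < 2 * n) {
    stop(sprintf("pooled samples (%d) cannot fill two populations of %d",
                 length(pool), n), call. = FALSE)
  }
  seeds <- derive_seeds(config$seed + 1L, n_permutations)
  counts <- integer(n_permutations)
  for (p in seq_len(n_permutations)) {
    set.seed(seeds[p])
    drawn <- sample(pool, 2L * n)
    plan <- build_gradient_plan(drawn[seq_len(n)], drawn[n + seq_len(n)], n)
    traj <- run_sweep(log_expr, plan, beta = config$beta, signed = config$signed)
    lfc <- log2_shift(quintilize(traj), config$epsilon)
    counts[p] <- sum(abs(lfc) > config$log2fc_threshold)
  }
  # inverse-ECDF quantiles: counts are discrete, so interpolating between
  # order statistics has no meaning for a permutation distribution
  bounds <- stats::quantile(counts, c(0.025, 0.975), names = FALSE, type = 1)
  list(counts = counts, lower = bounds[1], upper = bounds[2],
       n_permutations = n_permutations,
       threshold = config$log2fc_threshold, population_size = n)
}

#' Compare gradient threshold-passing counts with the permutation null
#'
#' @param bias_calls a `bias_call_table` from [run_consistency()].
#' @param null a [run_null()] result.
#' @return list with the mean gradient count, the null interval, and flags
#'   `within_interval` and `above_upper`.
#' @export
gradient_vs_null <- function(bias_calls, null) {
  counts <- attr(bias_calls, "iteration_counts")
  if (is.null(counts)) stop("'bias_calls' lacks iteration counts", call. = FALSE)
  m <- mean(counts)
  list(gradient_counts = counts, gradient_mean_count = m,
       null_lower = null$lower, null_upper = null$upper,
       within_interval = m >= null$lower & m <= null$upper,
       above_upper = m > null$upper)
}

#' Menopause variant of the sweep
#'
#' Within female samples, sweeps over the age-50 dichotomy (decades starting
#' below 50 form the premenopause group at the gradient's start, decades 50+
#' the postmenopause group at its end) using the identical machinery. If a
#' set of sex-biased genes is supplied, also reports what fraction of them is
#' menopause-affected.
#'
#' @param log_expr genes x samples log2 expression matrix (female samples).
#' @param metadata data.frame with `sample_id`, `sex`, `age_decade`; only
#'   female rows are used.
#' @param config a [sweep_config()].
#' @param biased_genes optional character vector of sex-biased gene IDs.
#' @param age_cut dichotomy point in years (default 50).
#' @return list with `calls` (a `bias_call_table` whose direction labels are
#'   `pre`/`post`), `affected` (menopause-affected gene IDs), and
#'   `overlap_fraction` (`NA` when `biased_genes` is missing or empty).
#' @export
menopause_sweep <- function(log_expr, metadata, config = sweep_config(),
                            biased_genes = NULL, age_cut = 50) {
  stopifnot(is.data.frame(metadata),
            all(c("sample_id", "sex", "age_decade") %in% names(metadata)))
  fem <- metadata[metadata$sex == "female" &
                    metadata$sample_id %in% colnames(log_expr), ]
  pre <- fem$sample_id[decade_start(fem$age_decade) < age_cut]
  post <- fem$sample_id[decade_start(fem$age_decade) >= age_cut]
  calls <- run_group_consistency(log_expr, pre, post, config,
                                 labels = c("pre", "post"))
  affected <- calls$gene_id[calls$is_sex_biased]
  overlap_fraction <- NA_real_
  if (!is.null(biased_genes)) {
    if (!length(biased_genes)) {
      warning("'biased_genes' is empty; overlap fraction undefined")
    } else {
      overlap_fraction <- length(intersect(biased_genes, affected)) /
        length(unique(biased_genes))
    }
  }
  list(calls = calls, affected = affected, overlap_fraction = overlap_fraction)
}
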