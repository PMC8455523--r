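# Synthetic TPM-scale expression with planted sex-dependent co-expression
# modules. The generator exists so the whole gradient-sweep pipeline can be
# exercised and validated without any external download: it plants modules
# whose within-module correlation is present (or stronger) in one sex,
# independent background genes, and optional mean-shift-only (DE) genes.

#' Specify one planted co-expression module
#'
#' A module is a block of genes sharing a single latent factor within the
#' samples of its target group. For a sample of group `s`, a module gene's
#' latent value is `sqrt(rho) * f + sqrt(1 - rho) * e` with `rho = rho_on`
#' when `s` matches `target_group` and `rho = rho_off` otherwise; `f` is the
#' module factor (one draw per sample) and `e` independent standard normal
#' noise. Within the active group every gene pair therefore has population
#' correlation `rho_on` on the latent (log2) scale.
#'
#' @param n_genes number of genes in the module (>= 2).
#' @param target_group one of `"male"`, `"female"`, `"both"`,
#'   `"premenopause_female"`. The last restricts the active set to female
#'   samples with age decade starting below 50, so the menopause variant of
#'   the sweep is testable.
#' @param rho_on within-module latent correlation in the active group, in
#'   `[0, 1)`.
#' @param rho_off correlation in all other samples, in `[0, rho_on]`.
#' @return a `module_spec` list.
#' @export
module_spec <- function(n_genes, target_group = c("male", "female", "both",
                                                  "premenopause_female"),
                        rho_on, rho_off = 0) {
  target_group <- match.arg(target_group)
  n_genes <- check_count(n_genes, "n_genes", min = 2)
  if (!is.numeric(rho_on) || rho_on < 0 || rho_on >= 1) {
    stop("'rho_on' must lie in [0, 1)", call. = FALSE)
  }
  if (!is.numeric(rho_off) || rho_off < 0 || rho_off >= 1) {
    stop("'rho_off' must lie in [0, 1)", call. = FALSE)
  }
  if (rho_off > rho_on) {
    stop("'rho_off' must not exceed 'rho_on'", call. = FALSE)
  }
  structure(list(n_genes = n_genes, target_group = target_group,
                 rho_on = rho_on, rho_off = rho_off),
            class = "module_spec")
}

#' Configure a synthetic expression dataset
#'
#' Defaults give per-gene log2 means around 7 and log2 standard deviation 1.5,
#' so every generated gene passes the default expression filters of
#' [select_genes()] (mean log2(TPM+1) >= 1, variance >= 1) and the planted
#' structure is never silently dropped by preprocessing.
#'
#' @param n_females,n_males numbers of samples per sex (each >= 5).
#' @param n_background_genes independent genes with no planted structure.
#' @param modules list of [module_spec()] objects.
#' @param n_de_genes mean-shift-only genes: uncorrelated, but with a
#'   sex-specific shift of `de_log2_shift` added to the log2 mean (alternating
#'   up-in-male / up-in-female), emulating differential expression without any
#'   co-expression signal.
#' @param de_log2_shift log2 units of the DE mean shift.
#' @param base_log2_mean baseline per-gene log2-TPM mean; individual genes
#'   jitter uniformly within +/- 0.5 of it.
#' @param gene_log2_sd per-gene log2-scale standard deviation (> 0).
#' @param age_decades data.frame with columns `decade` and `weight` giving the
#'   age-decade labels and their sampling weights; sampled independently of
#'   sex.
#' @param seed integer seed; identical seeds give bit-identical datasets.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_females = 100, n_males = 100,
                              n_background_genes = 250,
                              modules = list(),
                              n_de_genes = 0, de_log2_shift = 2,
                              base_log2_mean = 7, gene_log2_sd = 1.5,
                              age_decades = default_age_decades(),
                              seed = 1) {
  n_females <- check_count(n_females, "n_females", min = 5)
  n_males <- check_count(n_males, "n_males", min = 5)
  n_background_genes <- check_count(n_background_genes, "n_background_genes")
  n_de_genes <- check_count(n_de_genes, "n_de_genes")
  if (!is.numeric(gene_log2_sd) || gene_log2_sd <= 0) {
    stop("'gene_log2_sd' must be > 0", call. = FALSE)
  }
  if (!all(vapply(modules, inherits, logical(1), "module_spec"))) {
    stop("'modules' must be a list of module_spec objects", call. = FALSE)
  }
  stopifnot(is.data.frame(age_decades),
            all(c("decade", "weight") %in% names(age_decades)))
  structure(list(n_females = n_females, n_males = n_males,
                 n_background_genes = n_background_genes,
                 modules = modules, n_de_genes = n_de_genes,
                 de_log2_shift = de_log2_shift,
                 base_log2_mean = base_log2_mean,
                 gene_log2_sd = gene_log2_sd,
                 age_decades = age_decades,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' @rdname simulation_config
#' @export
default_age_decades <- function() {
  data.frame(decade = c("20-29", "30-39", "40-49", "50-59", "60-69", "70-79"),
             weight = 1, stringsAsFactors = FALSE)
}

#' Generate a synthetic TPM expression dataset with planted structure
#'
#' TPM values are synthesized as `2^(mu_g + sd_g * z) - 1`, floored at 0, so
#' that `log2(TPM + 1)` recovers the approximately Gaussian latent structure
#' the downstream pipeline assumes. Module genes share a per-sample latent
#' factor inside their active group (see [module_spec()]); background and DE
#' genes are mutually independent.
#'
#' @param config a [simulation_config()].
#' @return list with components:
#'   \describe{
#'     \item{expr}{genes x samples TPM matrix (dimnames set).}
#'     \item{metadata}{data.frame with `sample_id`, `sex`, `age_decade`,
#'       `rin`, `tissue`.}
#'     \item{truth}{planted truth: `genes` (gene_id, module, is_de,
#'       de_direction) and `modules` (module, target_group, rho_on, rho_off).}
#'   }
#' @export
generate_dataset <- function(config) {
  if (!inherits(config, "simulation_config")) {
    stop("'config' must come from simulation_config()", call. = FALSE)
  }
  set.seed(config$seed)
  n_f <- config$n_females
  n_m <- config$n_males
  n_s <- n_f + n_m
  sex <- rep(c("female", "male"), c(n_f, n_m))
  sample_id <- sprintf("%s%04d", ifelse(sex == "female", "F", "M"),
                       c(seq_len(n_f), seq_len(n_m)))
  age_decade <- sample(config$age_decades$decade, n_s, replace = TRUE,
                       prob = config$age_decades$weight)
  metadata <- data.frame(
    sample_id = sample_id,
    sex = sex,
    age_decade = age_decade,
    rin = round(stats::runif(n_s, 6.2, 9.8), 1),
    tissue = "synthetic",
    stringsAsFactors = FALSE
  )

  module_ids <- if (length(config$modules)) {
    sprintf("mod%d", seq_along(config$modules))
  } else character(0)

  blocks <- list()     # log2-scale latent blocks, later assembled
  gene_rows <- list()

  for (i in seq_along(config$modules)) {
    m <- config$modules[[i]]
    active <- switch(m$target_group,
      male = sex == "male",
      female = sex == "female",
      both = rep(TRUE, n_s),
      premenopause_female = sex == "female" & decade_start(age_decade) < 50
    )
    rho <- ifelse(active, m$rho_on, m$rho_off)
    f <- stats::rnorm(n_s)
    z <- matrix(stats::rnorm(m$n_genes * n_s), nrow = m$n_genes)
    z <- sweep(z, 2, sqrt(1 - rho), `*`) +
      matrix(rep(sqrt(rho) * f, each = m$n_genes), nrow = m$n_genes)
    ids <- sprintf("%s_g%03d", module_ids[i], seq_len(m$n_genes))
    rownames(z) <- ids
    blocks[[length(blocks) + 1L]] <- z
    gene_rows[[length(gene_rows) + 1L]] <- data.frame(
      gene_id = ids, module = module_ids[i], is_de = FALSE,
      de_direction = NA_character_, stringsAsFactors = FALSE)
  }

  if (config$n_background_genes > 0) {
    z <- matrix(stats::rnorm(config$n_background_genes * n_s),
                nrow = config$n_background_genes)
    ids <- sprintf("bg_g%03d", seq_len(config$n_background_genes))
    rownames(z) <- ids
    blocks[[length(blocks) + 1L]] <- z
    gene_rows[[length(gene_rows) + 1L]] <- data.frame(
      gene_id = ids, module = NA_character_, is_de = FALSE,
      de_direction = NA_character_, stringsAsFactors = FALSE)
  }

  de_shift <- NULL
  if (config$n_de_genes > 0) {
    z <- matrix(stats::rnorm(config$n_de_genes * n_s),
                nrow = config$n_de_genes)
    ids <- sprintf("de_g%03d", seq_len(config$n_de_genes))
    rownames(z) <- ids
    de_dir <- rep(c("male", "female"), length.out = config$n_de_genes)
    # shift applied on the log2-mean scale, to the favoured sex only
    de_shift <- matrix(0, nrow = config$n_de_genes, ncol = n_s)
    de_shift[de_dir == "male", sex == "male"] <- config$de_log2_shift
    de_shift[de_dir == "female", sex == "female"] <- config$de_log2_shift
    blocks[[length(blocks) + 1L]] <- z
    gene_rows[[length(gene_rows) + 1L]] <- data.frame(
      gene_id = ids, module = NA_character_, is_de = TRUE,
      de_direction = de_dir, stringsAsFactors = FALSE)
  }

  if (!length(blocks)) stop("config generates zero genes", call. = FALSE)
  z_all <- do.call(rbind, blocks)
  genes <- do.call(rbind, gene_rows)
  n_g <- nrow(z_all)

  mu <- config$base_log2_mean + stats::runif(n_g, -0.5, 0.5)
  log2_expr <- mu + config$gene_log2_sd * z_all
  if (!is.null(de_shift)) {
    idx <- which(genes$is_de)
    log2_expr[idx, ] <- log2_expr[idx, ] + de_shift
  }
  expr <- pmax(2^log2_expr - 1, 0)
  dimnames(expr) <- list(genes$gene_id, sample_id)

  modules_df <- if (length(config$modules)) {
    data.frame(
      module = module_ids,
      target_group = vapply(config$modules, `[[`, character(1), "target_group"),
      rho_on = vapply(config$modules, `[[`, numeric(1), "rho_on"),
      rho_off = vapply(config$modules, `[[`, numeric(1), "rho_off"),
      stringsAsFactors = FALSE)
  } else {
    data.frame(module = character(0), target_group = character(0),
               rho_on = numeric(0), rho_off = numeric(0))
  }

  list(expr = expr, metadata = metadata,
       truth = structure(list(genes = genes, modules = modules_df),
                         class = "synthetic_truth"))
}

#' Build a gene-set collection from planted truth
#'
#' One set per planted module (its exact genes) plus uniformly drawn decoy
#' sets, for validating over-representation analysis: the module sets should
#' rank top when the query is the recovered biased genes of the module's
#' target sex.
#'
#' @param truth the `truth` component of [generate_dataset()] output.
#' @param n_decoy_sets number of random decoy sets.
#' @param seed integer seed.
#' @param decoy_size_range integer range decoy sizes are drawn from.
#' @return a [gene_set_collection()] whose universe is every generated gene.
#' @export
generate_gene_sets <- function(truth, n_decoy_sets = 3, seed = 1,
                               decoy_size_range = c(10L, 30L)) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (!nrow(truth$genes)) stop("'truth' is empty", call. = FALSE)
  n_decoy_sets <- check_count(n_decoy_sets, "n_decoy_sets")
  universe <- truth$genes$gene_id
  sets <- list()
  for (m in truth$modules$module) {
    sets[[paste0("module_", m)]] <- truth$genes$gene_id[
      !is.na(truth$genes$module) & truth$genes$module == m]
  }
  set.seed(seed)
  lo <- min(decoy_size_range); hi <- min(max(decoy_size_range), length(universe))
  for (i in seq_len(n_decoy_sets)) {
    sz <- if (hi > lo) sample(lo:hi, 1) else lo
    sets[[sprintf("decoy_%d", i)]] <- sample(universe, min(sz, length(universe)))
  }
  gene_set_collection(sets, universe = universe)
}

#' Simulate a gene-disease association table with evidence scores
#'
#' Emulates the shape of curated gene-disease resources: rows of
#' (gene, disease, score) with scores in (0, 1]. Scores are uniform on (0, 1],
#' so the empirical 90th percentile of a large table approaches 0.9. One
#' disease ("disease_1") is guaranteed at least `n_major_genes` annotated
#' genes (capped at the universe size) so the per-disease size filter of
#' [filter_associations()] always has a surviving disease to act on.
#'
#' @param truth the `truth` component of [generate_dataset()] output.
#' @param n_diseases number of distinct disease labels (>= 1).
#' @param n_major_genes guaranteed annotation count for the first disease.
#' @param seed integer seed.
#' @return data.frame with columns `gene`, `disease`, `score`.
#' @export
generate_association_table <- function(truth, n_diseases = 5,
                                       n_major_genes = 100, seed = 1) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (!nrow(truth$genes)) stop("'truth' is empty", call. = FALSE)
  n_diseases <- check_count(n_diseases, "n_diseases", min = 1)
  universe <- truth$genes$gene_id
  set.seed(seed)
  rows <- list()
  for (d in seq_len(n_diseases)) {
    n_ann <- if (d == 1L) {
      min(n_major_genes, length(universe))
    } else {
      sample(5:min(50, length(universe)), 1)
    }
    rows[[d]] <- data.frame(
      gene = sample(universe, n_ann),
      disease = sprintf("disease_%d", d),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$score <- stats::runif(nrow(out), min = .Machine$double.eps, max = 1)
  rownames(out) <- NULL
  out
}
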