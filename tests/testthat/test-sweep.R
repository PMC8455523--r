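count_females <- function(pop, female_ids) sum(pop %in% female_ids)

test_that("gradient plans shift exactly one sample per step from all-female to all-male", {
  f <- sprintf("F%02d", 1:10)
  m <- sprintf("M%02d", 1:10)
  plan <- build_gradient_plan(f, m, population_size = 3, seed = 1)
  expect_length(plan, 4)
  expect_true(all(lengths(plan) == 3))
  expect_equal(vapply(plan, count_females, integer(1), female_ids = f),
               c(3L, 2L, 1L, 0L))
  for (k in 2:length(plan)) {
    sym_diff <- union(setdiff(plan[[k - 1]], plan[[k]]),
                      setdiff(plan[[k]], plan[[k - 1]]))
    expect_length(sym_diff, 2)
  }
  expect_identical(build_gradient_plan(f, m, 3, seed = 1), plan)
  expect_false(identical(build_gradient_plan(f, m, 3, seed = 2), plan))
  expect_error(build_gradient_plan(f[1:2], m, 3), "female")
  expect_error(build_gradient_plan(f, m[1], 3), "male")
})

test_that("run_sweep recomputes connectivity per population", {
  d <- planted_dataset()
  l <- log_transform(d$expr)[1:60, ]
  ids <- colnames(l)[1:10]
  # same population at every step: all trajectory columns identical
  plan <- rep(list(ids), 6)
  traj <- run_sweep(l, plan)
  expect_equal(ncol(traj), 6)
  expect_true(all(traj == traj[, 1]))
  expect_true(all(traj >= 0))
  expect_error(run_sweep(l, list(c("nope1", "nope2", "nope3"))), "absent")
  expect_error(run_sweep(l, list(ids[1:2])), ">= 3 samples")
})

test_that("male-module connectivity rises toward the all-male end of one sweep", {
  d <- planted_dataset()
  l <- log_transform(d$expr)
  f <- d$metadata$sample_id[d$metadata$sex == "female"]
  m <- d$metadata$sample_id[d$metadata$sex == "male"]
  plan <- build_gradient_plan(f, m, 80, seed = 3)
  traj <- run_sweep(l, plan)
  male_mod <- truth_genes(d$truth, "module", "mod1")
  expect_true(all(traj[male_mod, 81] > traj[male_mod, 1]))
})

test_that("quintilization follows the contiguous floor(5i/(n+1)) block rule", {
  traj10 <- matrix(rep(1:10, each = 2), 2, 10, byrow = FALSE,
                   dimnames = list(c("g1", "g2"), NULL))
  blocks10 <- table(floor(5 * (0:9) / 10))
  expect_equal(unname(c(blocks10)), c(2, 2, 2, 2, 2))
  blocks11 <- table(floor(5 * (0:10) / 11))
  expect_equal(unname(c(blocks11)), c(3, 2, 2, 2, 2))
  q <- quintilize(traj10)
  expect_equal(dim(q), c(2, 5))
  expect_equal(unname(q[1, ]), c(1.5, 3.5, 5.5, 7.5, 9.5))
  const <- matrix(2, 1, 11)
  expect_equal(unname(quintilize(const)[1, ]), rep(2, 5))
  expect_error(quintilize(matrix(1, 2, 4)), "at least 5")
})

test_that("log2 shift and per-iteration calls follow the strict threshold rules", {
  q <- rbind(up = c(2, 0, 0, 0, 8), flat = c(3, 0, 0, 0, 3),
             down = c(8, 0, 0, 0, 2))
  colnames(q) <- paste0("Q", 1:5)
  lfc <- log2_shift(q, epsilon = 0)
  expect_equal(unname(lfc), c(2, 0, -2))
  calls <- call_iteration(c(a = 1.2, b = -1.5, c = 1.0, d = -1.0, e = 0.3),
                          threshold = 1)
  expect_equal(unname(calls), c("male", "female", "none", "none", "none"))
})

test_that("reversing a sweep mirrors the log2 shift exactly when blocks are balanced", {
  d <- planted_dataset()
  l <- log_transform(d$expr)[1:80, ]
  f <- d$metadata$sample_id[d$metadata$sex == "female"]
  m <- d$metadata$sample_id[d$metadata$sex == "male"]
  plan <- build_gradient_plan(f, m, 9, seed = 4)  # 10 populations: blocks of 2
  traj <- run_sweep(l, plan)
  lfc <- log2_shift(quintilize(traj))
  lfc_rev <- log2_shift(quintilize(traj[, 10:1]))
  expect_equal(lfc_rev, -lfc, tolerance = 1e-12)
})

test_that("consistency filter applies the inclusive min-calls bound and majority direction", {
  lfc <- rbind(
    called20 = c(rep(1.5, 20), rep(0, 80)),
    called19 = c(rep(1.5, 19), rep(0, 81)),
    fem25 = c(rep(-1.4, 25), rep(0.2, 75)),
    tied = c(rep(1.5, 12), rep(-1.5, 12), rep(0, 76)))
  cfg <- sweep_config(n_iterations = 100, min_calls = 20)
  expect_warning(tab <- sexcoex:::finalize_bias_calls(lfc, cfg), "tied")
  expect_equal(tab$n_called, c(20L, 19L, 25L, 24L))
  expect_equal(tab$is_sex_biased, c(TRUE, FALSE, TRUE, TRUE))
  # direction reflects the majority among calling iterations even below the
  # consistency bound; only ties collapse to "none"
  expect_equal(tab$direction, c("male", "male", "female", "none"))
  expect_equal(attr(tab, "iteration_counts")[1], 4)  # 4 genes pass in iter 1
})

test_that("repeated sweeps recover planted modules with correct direction", {
  d <- planted_dataset()
  res <- planted_bias_calls()
  male_mod <- truth_genes(d$truth, "module", "mod1")
  fem_mod <- truth_genes(d$truth, "module", "mod2")
  bg <- truth_genes(d$truth, "background")
  called_male <- res$gene_id[res$is_sex_biased & res$direction == "male"]
  called_fem <- res$gene_id[res$is_sex_biased & res$direction == "female"]
  expect_gte(mean(male_mod %in% called_male), 0.8)
  expect_gte(mean(fem_mod %in% called_fem), 0.8)
  expect_lte(mean(bg %in% res$gene_id[res$is_sex_biased]), 0.05)
  # structural invariants of the call table
  expect_true(all(res$is_sex_biased == (res$n_called >= 20)))
  expect_true(all(res$direction[res$n_called == 0] == "none"))
  expect_identical(res$gene_id, rownames(d$expr))
})

test_that("menopause sweep recovers a planted premenopause module and reports overlap", {
  cfg <- simulation_config(
    n_females = 100, n_males = 5, n_background_genes = 75,
    modules = list(module_spec(25, "premenopause_female", rho_on = 0.9)),
    age_decades = data.frame(
      decade = c("20-29", "30-39", "40-49", "50-59", "60-69", "70-79"),
      weight = 1),
    seed = 77)
  d <- generate_dataset(cfg)
  fem <- d$metadata[d$metadata$sex == "female", ]
  n_pre <- sum(as.numeric(sub("-.*", "", fem$age_decade)) < 50)
  sc <- sweep_config(population_size = min(n_pre, nrow(fem) - n_pre),
                     n_iterations = 25, seed = 9)
  planted <- truth_genes(d$truth, "module", "mod1")
  res <- menopause_sweep(log_transform(d$expr), d$metadata, sc,
                         biased_genes = planted)
  recall <- mean(planted %in% res$affected)
  expect_gte(recall, 0.8)
  expect_equal(res$overlap_fraction,
               length(intersect(planted, res$affected)) / length(planted))
  # overlap fraction boundary behaviour
  res0 <- menopause_sweep(log_transform(d$expr), d$metadata, sc,
                          biased_genes = c("absent1", "absent2"))
  expect_equal(res0$overlap_fraction, 0)
  res1 <- menopause_sweep(log_transform(d$expr), d$metadata, sc,
                          biased_genes = res$affected)
  expect_equal(res1$overlap_fraction, 1)
})

test_that("undersized groups are rejected with the deficient group named", {
  d <- planted_dataset()
  l <- log_transform(d$expr)
  md <- d$metadata
  expect_error(
    run_consistency(l, md[c(1:5, 81:160), ], sweep_config(population_size = 10)),
    "female")
  expect_error(
    menopause_sweep(l, transform(md, age_decade = "60-69"),
                    sweep_config(population_size = 10)),
    "pre")
})
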