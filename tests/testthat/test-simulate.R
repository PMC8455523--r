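test_that("planted within-group correlation matches the module specification", {
  cfg <- simulation_config(
    n_females = 100, n_males = 100, n_background_genes = 0,
    modules = list(module_spec(2, "male", rho_on = 0.999, rho_off = 0)),
    seed = 11)
  d <- generate_dataset(cfg)
  l <- log_transform(d$expr)
  males <- d$metadata$sample_id[d$metadata$sex == "male"]
  females <- d$metadata$sample_id[d$metadata$sex == "female"]
  r_m <- cor(l[1, males], l[2, males])
  r_f <- cor(l[1, females], l[2, females])
  expect_gt(r_m, 0.9)
  expect_lt(abs(r_f), 3 / sqrt(length(females)))
})

test_that("average within-module correlation converges to rho_on in the active group", {
  cfg <- simulation_config(
    n_females = 500, n_males = 5, n_background_genes = 0,
    modules = list(module_spec(10, "female", rho_on = 0.6, rho_off = 0)),
    seed = 12)
  d <- generate_dataset(cfg)
  l <- log_transform(d$expr)
  females <- d$metadata$sample_id[d$metadata$sex == "female"]
  r <- cor(t(l[, females]))
  mean_r <- mean(r[upper.tri(r)])
  expect_lt(abs(mean_r - 0.6), 0.05)
})

test_that("background gene correlations are centered at zero", {
  cfg <- simulation_config(n_females = 100, n_males = 100,
                           n_background_genes = 60, seed = 13)
  d <- generate_dataset(cfg)
  r <- cor(t(log_transform(d$expr)))
  off <- r[upper.tri(r)]
  # mean of ~1770 null correlations, each ~N(0, 1/198)
  expect_lt(abs(mean(off)), 4 / sqrt(198 * length(off)) + 0.01)
})

test_that("generated datasets are deterministic under a fixed seed and pass the gene filters", {
  cfg <- simulation_config(
    n_females = 30, n_males = 30, n_background_genes = 40,
    modules = list(module_spec(5, "both", rho_on = 0.5)),
    n_de_genes = 4, seed = 99)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$expr, d2$expr)
  expect_identical(d1$metadata, d2$metadata)
  expect_identical(d1$truth, d2$truth)
  # planted genes must never be silently dropped by preprocessing
  expect_setequal(select_genes(d1$expr), rownames(d1$expr))
  expect_true(all(d1$expr >= 0))
  expect_equal(nrow(d1$expr), 5 + 40 + 4)
  expect_equal(ncol(d1$expr), 60)
})

test_that("invalid simulation configs are rejected with the violated bound named", {
  expect_error(simulation_config(n_females = 4), "n_females")
  expect_error(simulation_config(gene_log2_sd = 0), "gene_log2_sd")
  expect_error(module_spec(1, "male", 0.5), "n_genes")
  expect_error(module_spec(3, "male", rho_on = 0.2, rho_off = 0.4), "rho_off")
  expect_error(module_spec(3, "male", rho_on = 1), "rho_on")
})

test_that("premenopause modules are active only in young female samples", {
  cfg <- simulation_config(
    n_females = 200, n_males = 5, n_background_genes = 0,
    modules = list(module_spec(6, "premenopause_female", rho_on = 0.8)),
    seed = 21)
  d <- generate_dataset(cfg)
  l <- log_transform(d$expr)
  fem <- d$metadata[d$metadata$sex == "female", ]
  young <- fem$sample_id[as.numeric(sub("-.*", "", fem$age_decade)) < 50]
  old <- fem$sample_id[as.numeric(sub("-.*", "", fem$age_decade)) >= 50]
  r_young <- cor(t(l[, young]))
  r_old <- cor(t(l[, old]))
  expect_gt(mean(r_young[upper.tri(r_young)]), 0.6)
  expect_lt(abs(mean(r_old[upper.tri(r_old)])), 0.15)
})

test_that("gene-set fixtures mirror the planted modules plus seeded decoys", {
  d <- planted_dataset()
  gs <- generate_gene_sets(d$truth, n_decoy_sets = 3, seed = 5)
  expect_length(gs$sets, 2 + 3)
  expect_setequal(gs$sets$module_mod1, truth_genes(d$truth, "module", "mod1"))
  expect_length(gs$sets$module_mod1, 25)
  gs2 <- generate_gene_sets(d$truth, n_decoy_sets = 3, seed = 5)
  expect_identical(gs$sets, gs2$sets)
})

test_that("association-table fixture has the requested diseases and uniform scores", {
  d <- planted_dataset()
  tab <- generate_association_table(d$truth, n_diseases = 5,
                                    n_major_genes = 100, seed = 31)
  expect_equal(length(unique(tab$disease)), 5)
  expect_true(all(tab$score > 0 & tab$score <= 1))
  expect_gte(sum(tab$disease == "disease_1"), 100)
  # Monte-Carlo check: empirical 90th percentile of many uniform scores ~ 0.9
  big <- do.call(rbind, lapply(1:40, function(s) {
    generate_association_table(d$truth, n_diseases = 5, seed = s)
  }))
  expect_lt(abs(quantile(big$score, 0.9) - 0.9), 0.02)
  empty <- structure(list(genes = data.frame(), modules = data.frame()),
                     class = "synthetic_truth")
  expect_error(generate_association_table(empty), "empty")
})
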