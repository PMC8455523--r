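test_that("GMT parsing deduplicates members and round-trips", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("S1\tdesc\tA\tB\tB", "S2\tother\tC\tD"), path)
  gs <- read_gmt(path)
  expect_setequal(gs$sets$S1, c("A", "B"))
  expect_length(gs$sets$S1, 2)
  out <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(gs, out)
  expect_identical(read_gmt(out)$sets, gs$sets)
  empty <- withr::local_tempfile(fileext = ".gmt")
  writeLines(character(0), empty)
  expect_length(read_gmt(empty)$sets, 0)
  bad <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("S1\tdesc\tA", "justonefield\ttwo"), bad)
  expect_error(read_gmt(bad), "line 2")
})

test_that("ORA reproduces the closed-form hypergeometric tail", {
  universe <- sprintf("g%02d", 1:20)
  gs <- gene_set_collection(list(hit = universe[1:5]), universe = universe)
  res <- ora(universe[1:5], gs)
  expect_equal(res$p_value, 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(res$p_value, 6.450e-5, tolerance = 1e-3)
  expect_equal(res$overlap, 5)
  # query = universe: overlap is certain, p = 1
  res_all <- ora(universe, gs)
  expect_equal(res_all$p_value, 1)
  expect_equal(res_all$overlap, 5)
})

test_that("ORA matches the combinatorial enumeration oracle on small instances", {
  for (N in c(6, 9, 12)) {
    universe <- paste0("u", seq_len(N))
    for (m in 0:N) {
      gs <- gene_set_collection(list(s = universe[seq_len(m)]),
                                universe = universe)
      for (q in 1:N) {
        for (k in max(0, q + m - N):min(m, q)) {
          query <- c(universe[seq_len(k)],
                     universe[setdiff(seq_len(N), seq_len(m))][seq_len(q - k)])
          res <- ora(query, gs)
          expect_equal(res$p_value, hyper_tail_oracle(k, m, N, q),
                       tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("ORA p-value is monotone non-increasing in the overlap", {
  N <- 30; m <- 10; q <- 8
  ps <- vapply(0:min(m, q), function(k) {
    phyper(k - 1, m, N - m, q, lower.tail = FALSE)
  }, numeric(1))
  expect_true(all(diff(ps) <= 0))
})

test_that("ORA handles out-of-universe queries and empty results", {
  universe <- paste0("g", 1:10)
  gs <- gene_set_collection(list(s = universe[1:3]), universe = universe)
  expect_warning(res <- ora(c(universe[1], "alien"), gs), "outside the universe")
  expect_equal(res$query_size, 1)
  expect_warning(res0 <- ora(character(0), gs), "empty")
  expect_equal(nrow(res0), 0)
})

test_that("planted-module sets top-rank when queried with their own genes", {
  d <- planted_dataset()
  gs <- generate_gene_sets(d$truth, n_decoy_sets = 5, seed = 6)
  res <- planted_bias_calls()
  called_male <- res$gene_id[res$is_sex_biased & res$direction == "male"]
  enr <- ora(called_male, gs)
  expect_equal(enr$term[1], "module_mod1")
  expect_true(enr$significant[1])
})

test_that("compare_clusters stacks per-set results and codes significance", {
  universe <- paste0("g", 1:40)
  gs <- gene_set_collection(list(A = universe[1:8], B = universe[31:38]),
                            universe = universe)
  cc <- compare_clusters(list(female = universe[1:8], male = universe[31:38]),
                         gs)
  expect_setequal(unique(cc$query_set), c("female", "male"))
  # identical queries give identical rows
  cc_dup <- compare_clusters(list(x = universe[1:8], y = universe[1:8]), gs)
  expect_equal(cc_dup[cc_dup$query_set == "x", -1],
               cc_dup[cc_dup$query_set == "y", -1], ignore_attr = TRUE)
  codes <- significance_codes(cc, c("female", "male"))
  expect_equal(codes$code[codes$term == "A"], "female")
  expect_equal(codes$code[codes$term == "B"], "male")
  cc_both <- compare_clusters(list(female = universe[1:8],
                                   male = universe[c(1:6, 31:32)]), gs)
  codes_both <- significance_codes(cc_both, c("female", "male"))
  expect_equal(codes_both$code[codes_both$term == "A"], "both")
})

test_that("association filtering applies the inclusive size and interpolated quantile rules", {
  tab99 <- data.frame(gene = paste0("g", 1:99), disease = "d1",
                      score = runif(99))
  expect_equal(nrow(filter_associations(tab99, min_genes_per_disease = 100)), 0)
  tab100 <- data.frame(gene = paste0("g", 1:100), disease = "d1",
                       score = as.numeric(1:100))
  out <- filter_associations(tab100, min_genes_per_disease = 100,
                             score_quantile = 0.90)
  expect_equal(attr(out, "score_threshold"), 90.1)
  expect_equal(nrow(out), 10)
  expect_setequal(out$score, 91:100)
  tied <- data.frame(gene = paste0("g", 1:100), disease = "d1", score = 0.5)
  expect_equal(nrow(filter_associations(tied, 100)), 100)
  empty <- tab100[0, ]
  expect_equal(nrow(filter_associations(empty)), 0)
})
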