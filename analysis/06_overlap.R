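#!/usr/bin/env Rscript
# Step 6: set-overlap statistics.
#
# (a) Permutation test of the overlap between sex-biased disease genes and a
#     drug-target-style list, against size-matched draws from the
#     non-sex-biased analyzed genes (10,000 permutations).
# (b) Overlap between the planted differential-expression lists (the
#     synthetic stand-in for an external DE analysis) and the sex-biased
#     gene lists, to show the two signals are distinct.

library(sexcoex)
library(jsonlite)

calls <- read.table("results/sweep/bias_calls.tsv", header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
filt <- read.table("results/enrichment/associations_filtered.tsv",
                   header = TRUE, sep = "\t", stringsAsFactors = FALSE)
truth <- read_truth_json("results/data/truth.json")
out_dir <- "results/overlap"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

biased <- calls$gene_id[calls$is_sex_biased]
non_biased <- setdiff(calls$gene_id, biased)
disease_genes <- unique(filt$gene)

# drug-target stand-in: the planted module genes plus random non-module genes,
# i.e. a target list genuinely enriched for sex-biased co-expression
set.seed(9)
module_genes <- truth$genes$gene_id[!is.na(truth$genes$module)]
drug_targets <- unique(c(module_genes, sample(non_biased, 30)))

biased_disease <- intersect(biased, disease_genes)
res <- overlap_permutation_test(
  query_set = biased,
  target_set = drug_targets,
  permutation_pool = non_biased,
  n_perm = 10000, seed = 10)
print(res)
cat(sprintf("(diagnostic: proportion of null overlaps below observed = %.4f)\n",
            res$prop_lower))

de_m <- truth$genes$gene_id[truth$genes$is_de & truth$genes$de_direction == "male"]
de_f <- truth$genes$gene_id[truth$genes$is_de & truth$genes$de_direction == "female"]
ovr <- de_bias_overlap(de_f, de_m,
                       calls$gene_id[calls$is_sex_biased & calls$direction == "female"],
                       calls$gene_id[calls$is_sex_biased & calls$direction == "male"])
cat("DE vs co-expression-bias overlap (expected near zero):\n")
print(ovr, row.names = FALSE)

write_json(list(observed_overlap = res$observed_overlap,
                p_value = res$p_value, prop_lower = res$prop_lower,
                n_perm = res$n_perm,
                n_biased_disease_genes = length(biased_disease)),
           file.path(out_dir, "drug_target_overlap.json"),
           auto_unbox = TRUE, digits = NA)
write.table(ovr, file.path(out_dir, "de_bias_overlap.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
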