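#!/usr/bin/env Rscript
# Step 1: build the synthetic study dataset.
#
# 160 samples (80 female, 80 male), 320 genes: a 25-gene module co-expressed
# only in males, a 25-gene module co-expressed only in females (latent
# correlation 0.9 in the active sex, 0 otherwise), 250 independent background
# genes, and 20 mean-shift-only (DE) genes with no co-expression structure.
# Also writes the gene-set and gene-disease annotation fixtures used by the
# enrichment steps.

library(sexcoex)

out_dir <- "results/data"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

cfg <- simulation_config(
  n_females = 80, n_males = 80,
  n_background_genes = 250,
  modules = list(module_spec(25, "male", rho_on = 0.9, rho_off = 0),
                 module_spec(25, "female", rho_on = 0.9, rho_off = 0)),
  n_de_genes = 20,
  seed = 42)
d <- generate_dataset(cfg)

write_expression_tsv(d$expr, file.path(out_dir, "expression_tpm.tsv"))
write_metadata_tsv(d$metadata, file.path(out_dir, "metadata.tsv"))
write_truth_json(d$truth, file.path(out_dir, "truth.json"))

gs <- generate_gene_sets(d$truth, n_decoy_sets = 5, seed = 43)
write_gmt(gs, file.path(out_dir, "gene_sets.gmt"))

assoc <- generate_association_table(d$truth, n_diseases = 5,
                                    n_major_genes = 100, seed = 44)
write.table(assoc, file.path(out_dir, "gene_disease.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("Simulated %d genes x %d samples (%d planted module genes, %d DE-only).\n",
            nrow(d$expr), ncol(d$expr),
            sum(!is.na(d$truth$genes$module)), sum(d$truth$genes$is_de)))
cat("Wrote expression, metadata, truth, gene sets, and associations to", out_dir, "\n")
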