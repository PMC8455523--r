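#!/usr/bin/env Rscript
# Step 2: sample/tissue/gene selection and PCA QC.
#
# Applies the quality rules used for population RNA-seq cohorts: samples need
# RIN strictly above 6.0, a tissue needs at least 80 samples of each sex, and
# genes need mean log2(TPM+1) >= 1 with variance >= 1. PCA scores on the most
# variable genes are written for visual QC of sample structure.

library(sexcoex)

expr <- read_expression_tsv("results/data/expression_tpm.tsv")
meta <- read_metadata_tsv("results/data/metadata.tsv")
out_dir <- "results/preprocess"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

kept_samples <- filter_samples(meta, rin_min = 6.0)
meta <- meta[meta$sample_id %in% kept_samples, ]
cat(sprintf("RIN > 6.0 retained %d of %d samples.\n",
            length(kept_samples), ncol(expr)))

tissues <- select_tissues(meta, min_samples_per_sex = 80)
cat("Tissues with >= 80 samples of both sexes:",
    paste(tissues, collapse = ", "), "\n")
meta <- meta[meta$tissue %in% tissues, ]
expr <- expr[, meta$sample_id]

genes <- select_genes(expr, mean_log2_tpm_min = 1, var_log2_min = 1)
cat(sprintf("Gene filters retained %d of %d genes.\n", length(genes), nrow(expr)))
expr <- expr[genes, ]

qc <- pca_qc(expr, n_top_genes = 1000)
cat(sprintf("PC1/PC2 explain %.1f%% / %.1f%% of variance.\n",
            100 * qc$var_explained[1], 100 * qc$var_explained[2]))

write_expression_tsv(expr, file.path(out_dir, "expression_filtered.tsv"))
write_metadata_tsv(meta, file.path(out_dir, "metadata_filtered.tsv"))
write.table(qc$scores, file.path(out_dir, "pca_scores.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
writeLines(genes, file.path(out_dir, "genes_retained.txt"))
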