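#!/usr/bin/env Rscript
# Step 5: over-representation of the sex-biased gene lists against the
# gene-set collection (exact hypergeometric, significant at raw p < 0.05),
# per-sex significance codes, and evidence-score filtering of the
# gene-disease association table.

library(sexcoex)

calls <- read.table("results/sweep/bias_calls.tsv", header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
gs <- read_gmt("results/data/gene_sets.gmt")
assoc <- read.table("results/data/gene_disease.tsv", header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
out_dir <- "results/enrichment"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

# universe = every gene that entered the sweep
universe <- calls$gene_id
queries <- list(
  female = calls$gene_id[calls$is_sex_biased & calls$direction == "female"],
  male = calls$gene_id[calls$is_sex_biased & calls$direction == "male"])

cc <- compare_clusters(queries, gs, universe = universe)
codes <- significance_codes(cc, c("female", "male"))
top <- cc[cc$significant, c("query_set", "term", "overlap", "set_size", "p_value")]
cat("Significant enrichments (p < 0.05):\n")
print(top, row.names = FALSE)
cat("Per-term significance codes:",
    paste(sprintf("%s=%s", codes$term, codes$code), collapse = ", "), "\n")

write.table(cc, file.path(out_dir, "enrichment_long.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(codes, file.path(out_dir, "significance_codes.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

filt <- filter_associations(assoc, min_genes_per_disease = 100,
                            score_quantile = 0.90)
cat(sprintf("Association filter: %d of %d rows kept (diseases with >= 100 genes, score >= %.3f).\n",
            nrow(filt), nrow(assoc), attr(filt, "score_threshold")))
write.table(filt, file.path(out_dir, "associations_filtered.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
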