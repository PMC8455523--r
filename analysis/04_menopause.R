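#!/usr/bin/env Rscript
# Step 4: menopause variant -- the same sweep within females over the age-50
# dichotomy (decades 20-49 vs 50-79), and the fraction of sex-biased genes
# that are also menopause-affected.

library(sexcoex)

expr <- read_expression_tsv("results/preprocess/expression_filtered.tsv")
meta <- read_metadata_tsv("results/preprocess/metadata_filtered.tsv")
calls <- read.table("results/sweep/bias_calls.tsv", header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
out_dir <- "results/menopause"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

fem <- meta[meta$sex == "female", ]
n_pre <- sum(as.numeric(sub("-.*", "", fem$age_decade)) < 50)
n_post <- nrow(fem) - n_pre
cat(sprintf("Female samples: %d premenopause (< 50), %d postmenopause.\n",
            n_pre, n_post))

cfg <- sweep_config(population_size = min(n_pre, n_post),
                    n_iterations = 25, min_calls = 20, seed = 8)
biased <- calls$gene_id[calls$is_sex_biased]
res <- menopause_sweep(log_transform(expr), meta, cfg, biased_genes = biased)

cat(sprintf("Menopause-affected genes: %d; %.0f%% of the %d sex-biased genes are also menopause-affected.\n",
            length(res$affected), 100 * res$overlap_fraction, length(biased)))

write_bias_calls_tsv(res$calls, file.path(out_dir, "menopause_calls.tsv"))
writeLines(res$affected, file.path(out_dir, "menopause_affected.txt"))
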