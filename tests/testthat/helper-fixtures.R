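# Shared synthetic fixtures, generated once per test run and cached.

fixture_cache <- new.env(parent = emptyenv())

# The planted-module recovery dataset: 25 male-module + 25 female-module genes
# at rho_on 0.9 / rho_off 0, 250 independent background genes, 80 samples per
# sex. Optionally extended with mean-shift-only (DE) genes.
planted_dataset <- function(n_de_genes = 0) {
  key <- paste0("planted_", n_de_genes)
  if (!exists(key, envir = fixture_cache)) {
    cfg <- simulation_config(
      n_females = 80, n_males = 80, n_background_genes = 250,
      modules = list(module_spec(25, "male", rho_on = 0.9, rho_off = 0),
                     module_spec(25, "female", rho_on = 0.9, rho_off = 0)),
      n_de_genes = n_de_genes,
      seed = 42)
    assign(key, generate_dataset(cfg), envir = fixture_cache)
  }
  get(key, envir = fixture_cache)
}

# Bias calls on the planted dataset at the stated study conditions
# (25 iterations, defaults otherwise), cached because several tests reuse it.
planted_bias_calls <- function(n_de_genes = 0) {
  key <- paste0("calls_", n_de_genes)
  if (!exists(key, envir = fixture_cache)) {
    d <- planted_dataset(n_de_genes)
    cfg <- sweep_config(n_iterations = 25, seed = 7)
    assign(key, run_consistency(log_transform(d$expr), d$metadata, cfg),
           envir = fixture_cache)
  }
  get(key, envir = fixture_cache)
}

# Gene IDs by planted role.
truth_genes <- function(truth, role = c("module", "background", "de"),
                        module = NULL) {
  role <- match.arg(role)
  g <- truth$genes
  switch(role,
    module = g$gene_id[!is.na(g$module) &
                         (is.null(module) | g$module %in% module)],
    background = g$gene_id[is.na(g$module) & !g$is_de],
    de = g$gene_id[g$is_de])
}
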