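# sexcoex

Sex-biased gene co-expression via population gradient sweeps.

## The problem

Most sex-aware transcriptomics asks whether a gene's *expression level*
differs between males and females. This package asks a different question:
does a gene's *co-expression* — how strongly it is wired to the rest of the
transcriptome — depend on sex? A gene can sit at identical expression in both
sexes yet be tightly co-regulated with a module of partners in only one of
them. That signal is invisible to differential expression and requires a
network statistic computed separately in populations of different sex
composition.

The package is aimed at analysts working with bulk RNA-seq cohorts that carry
donor sex, age, and RNA-quality annotations (TPM matrices plus sample
metadata), and at method developers who want the detection machinery together
with a generator of synthetic data with planted, sex-dependent co-expression
to validate against.

## The method

For each gene *i*, co-expression strength in a sample set is the
soft-threshold **connectivity**

&nbsp;&nbsp;&nbsp;&nbsp;*k*ᵢ = Σ_{j≠i} |cor(xᵢ, xⱼ)|⁵

— Pearson correlation of log2(TPM+1) values raised to the WGCNA-style
exponent β = 5, summed over all other genes.

One **gradient sweep** builds n+1 equal-size populations: step 0 is n random
female samples; each step removes one random female and adds one random male;
step n is all-male. Connectivity is recomputed in every population, each
gene's trajectory is **quintilized** (five contiguous population blocks,
per-block median), and the gene's shift is the log2-fold change between the
extreme quintiles, log2(Q5/Q1). A gene is called in that iteration when
|log2FC| > 1 (male-biased if positive, female-biased if negative). The whole
sweep is repeated (100 iterations by default) with fresh random samples, and
a gene is labelled **sex-biased** when it is called in at least 20
iterations.

Calibration comes from a **permutation null**: the identical procedure with
populations drawn uniformly from the pooled sexes instead of a sex gradient.
The 2.5/97.5 percentiles of the per-permutation counts of threshold-passing
genes give the 95% interval the gradient counts are compared against.

The same machinery run within females over the age-50 dichotomy gives the
**menopause variant**. Downstream, biased gene lists feed an exact
hypergeometric over-representation test against GMT collections (significant
at raw p < 0.05), evidence-score filtering of gene-disease tables (diseases
with ≥ 100 genes, scores at or above their 90th percentile), and
size-matched set-overlap permutation tests (e.g. against drug-target lists;
10,000 permutations).

## Worked example

The numbered drivers under `analysis/` run the full workflow on a synthetic
cohort (80 females, 80 males; a 25-gene male-only module and a 25-gene
female-only module at latent correlation 0.9; 250 background genes; 20
mean-shift-only DE genes):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_preprocess.R
Rscript analysis/03_sweep.R      # the core sweep
Rscript analysis/04_menopause.R
Rscript analysis/05_enrichment.R
Rscript analysis/06_overlap.R
```

Step 3 prints:

```
Sex-biased genes: 28 male-biased, 26 female-biased of 320 tested (16.9%).
Mean per-iteration gradient count 67.7 vs null 95% interval [20, 62] -- gradient dominates the null.
```

The 25 + 25 planted module genes are recovered (the extra three calls are
background genes whose chance correlation with a module factor is a fixed
feature of the finite dataset), and the gradient's count of
threshold-passing genes exceeds the random-population null's upper bound.
Step 5 then finds exactly the two planted module sets enriched
(p ≈ 2e-36 and 3e-34, coded `female` and `male`), and step 6's permutation
test of biased genes against a module-enriched target list returns the floor
p-value 9.999e-05 with observed overlap 50 vs a null mean of ~6. The DE/bias
overlap table is all zeros: mean-shift-only genes are not mistaken for
co-expression bias.

Equivalent calls in R:

```r
library(sexcoex)
cfg <- simulation_config(
  n_females = 80, n_males = 80, n_background_genes = 250,
  modules = list(module_spec(25, "male", rho_on = 0.9),
                 module_spec(25, "female", rho_on = 0.9)),
  seed = 42)
d <- generate_dataset(cfg)
calls <- run_consistency(log_transform(d$expr), d$metadata,
                         sweep_config(n_iterations = 25, seed = 7))
head(calls[calls$is_sex_biased, ])
```

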