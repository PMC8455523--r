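---
title: "Detecting sex-biased gene co-expression with population gradient sweeps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting sex-biased gene co-expression with population gradient sweeps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sexcoex)
```

## The model and its assumptions

Differential *expression* compares means; differential *co-expression*
compares wiring. The statistic tracked here is each gene's whole-network
soft-threshold connectivity,

$$k_i = \sum_{j \ne i} |r_{ij}|^{\beta}, \qquad \beta = 5,$$

with $r_{ij}$ the Pearson correlation of $\log_2(\mathrm{TPM}+1)$ values
across the samples of one population. Raising $|r|$ to the fifth power is the
unsigned WGCNA convention: it suppresses the sea of weak, noise-level
correlations and lets $k_i$ be dominated by a gene's strong partners. The
unsigned transform means positive and negative co-regulation count equally;
a signed variant $((1+r)/2)^\beta$ is available behind a flag but is not the
default, matching common practice when no direction is asserted.

The detection procedure embeds $k_i$ in a **population gradient**. For
populations of fixed size $n$ (default: the smaller sex's sample count, so
both ends of the gradient are equally powered), step 0 holds $n$ random
females; every step removes one random remaining female and adds one random
unused male; step $n$ is all-male. Connectivity is recomputed in each of the
$n+1$ populations. If a gene's module is wired only in males, its trajectory
climbs from near zero to a plateau as males replace females; if wiring is
sex-independent, the trajectory is flat up to estimation noise.

Two assumptions matter. First, connectivity estimated from $n$ samples is
noisy, and consecutive populations share $n-1$ samples, so the trajectory is
strongly autocorrelated — which is why the trajectory is summarized by
**quintile medians** rather than by its raw endpoints: the $n+1$ populations
are split into five contiguous blocks by $\mathrm{block}(i) = \lfloor 5i/(n+1)
\rfloor$ (sizes differ by at most one; the rule is deterministic so results
do not depend on a tie-break), and each gene gets the per-block median. The
bias statistic is $\log_2\!\big((Q_5+\varepsilon)/(Q_1+\varepsilon)\big)$:
positive toward males, negative toward females. Second, a single sweep is
one random subsample; its calls reflect both signal and the luck of that
draw. The procedure is therefore repeated (100 iterations by default, each
with a fresh subsample and shift order, child seeds derived from one master
seed), and only genes called in at least 20 iterations — strict
$|\log_2\mathrm{FC}| > 1$ per iteration, inclusive $\ge 20$ overall — are
labelled sex-biased. Direction is the majority vote among calling
iterations; ties are reported with a warning and left uncalled rather than
silently resolved.

## Calibration against a permutation null

How many genes would pass the threshold with no sex structure at all? The
null runs the identical machinery with both pseudo-groups drawn uniformly
from the pooled sexes, so every population is a random mixed sample and the
"gradient" carries no sex information. Per permutation, the count of genes
with $|\log_2\mathrm{FC}|$ above threshold is recorded; the 2.5th/97.5th
percentiles of those counts form the 95% null interval. Because the counts
are small integers, the percentile bounds use the inverse-ECDF quantile
estimator (`type = 1`) — interpolating between order statistics of a discrete
permutation distribution would manufacture non-attainable bounds.

Two properties of this null are worth knowing. With few permutations the
empirical percentile interval is necessarily narrower than the true one: an
interval built from $P$ draws covers a new exchangeable draw with
probability at most about $(P-1)/(P+1)$, so calibration checks need $P$ in
the tens to hundreds before ~95% coverage is meaningful; the package default
matches the iteration count (100). And on data that *do* contain
sex-dependent modules, a random split can be sex-imbalanced by chance,
partially recreating the gradient; the fifth-power amplification means
occasional null permutations with inflated counts. The gradient still
dominates the null on average, but at a handful of permutations the null
maximum is a noisy bound.

## The menopause variant

Within females, the same sweep runs over an age dichotomy at 50 years
(decade labels "20–29" … "40–49" versus "50–59" and above), chosen because
menopause typically falls near that age. Group sizes follow the cohort's age
distribution, so `population_size` should be set to the smaller group. The
overlap fraction reported is $|\text{biased} \cap \text{affected}| /
|\text{biased}|$ against a supplied sex-biased gene list.

## Preprocessing rules

Samples require RIN strictly greater than 6.0 (a sample at exactly 6.0 is
excluded; missing RIN excludes with a warning). Tissues require at least 80
samples of *each* sex — inclusive, so 80/80 qualifies. Genes require, on the
$\log_2(\mathrm{TPM}+1)$ scale, mean $\ge 1$ and unbiased ($n-1$) variance
$\ge 1$. The pseudocount 1 makes TPM 0 map to 0 and is the same constant the
correlation analysis uses, so the filters act on exactly the analyzed scale.
The mean filter is read as "mean of the log values": the one-sentence rule it
implements couples the expression and variance cut-offs on a single scale,
and the variance cut-off is only meaningful on the log scale. PCA QC ranks
genes by log-scale variance, takes the top 1000 (capped at the gene count,
with a note), and returns the first two component scores for plotting only —
nothing downstream consumes them.

## Enrichment and overlap statistics

Over-representation uses the exact hypergeometric upper tail
$P(X \ge k)$ for overlap $k$, set size $m$, query size $q$, universe $N$,
via `stats::phyper`. The universe is the set of genes that entered the sweep
for that tissue — bias is tested among analyzed genes, not against the whole
genome. Significance is raw $p < 0.05$ by design; a Benjamini–Hochberg
column is emitted for readers who want it but does not feed the flag.
Gene-disease association tables are filtered in two sequential steps:
diseases with at least 100 annotated genes, then rows with evidence score at
or above the 90th percentile of the surviving scores (linear-interpolation
quantile — scores are continuous, unlike permutation counts).

Set-overlap significance uses size-matched draws without replacement from a
declared pool (non-biased analyzed genes), with the upper-tail add-one
estimator $p = (1 + \#\{\text{null} \ge \text{obs}\})/(P+1)$, whose floor at
$P = 10{,}000$ is $9.999\times10^{-5}$. The raw proportion of null overlaps
below the observed value is also returned as a diagnostic, since that
quantity is sometimes quoted directly.

## What the synthetic generator emulates — and what it does not

Each planted module shares one latent factor per sample within its active
group: gene $g$ in module $m$ has latent value $\sqrt{\rho}\,f_m +
\sqrt{1-\rho}\,\varepsilon_g$ with $\rho = \rho_\mathrm{on}$ in the target
group and $\rho_\mathrm{off}$ elsewhere, so every within-module pair has
population correlation $\rho_\mathrm{on}$ exactly where the module is
active. TPM values are synthesized as $2^{\mu_g + \sigma_g z} - 1$ floored
at zero, so the pipeline's own $\log_2(\mathrm{TPM}+1)$ transform recovers
the Gaussian latent structure. Defaults ($\mu_g \approx 7$,
$\sigma_g = 1.5$) keep every generated gene above the expression and
variance filters, so planted structure is never silently dropped. DE-only
genes add a sex-specific mean shift (2 log2 units by default) with *no*
correlation structure, which is what lets the tests demonstrate that
differential expression and co-expression bias are distinct signals. Age
decades are sampled independently of sex; premenopause modules switch on
only for females in decades below 50.

The generator deliberately omits much of what real cohorts contain:
library-size and count noise, tissue composition, batch and covariate
confounding, correlated filters (RIN is drawn in a passing range), and
overlapping or nested modules. Passing tests therefore demonstrate that the
machinery detects the planted statistical structure at realistic sizes — not
that real-tissue estimates carry the same error rates. One finite-sample
effect does carry over and is visible even in synthetic runs: with
population size equal to the full per-sex sample count, the sex split is a
single fixed partition, so chance correlations in that particular dataset
act as a fixed effect across all iterations, and a few background genes can
be called consistently. This mirrors the real-data situation, where an
analyst cannot distinguish "true in this cohort by chance" from "true in the
population" without replication.

## Numerical choices

* $\varepsilon = 10^{-6}$ inside the log ratio guards zero medians; after
  soft thresholding, any truly co-expressed gene has connectivity orders of
  magnitude above it, so the choice does not affect calls.
* Zero-variance genes within a population get correlation 0 (with a warning)
  rather than NaN, keeping adjacency sums finite.
* The adjacency diagonal is set to 0 before summation, bounding $k$ by
  $G - 1$; fold changes are insensitive to this constant-dimension
  convention.
* Reproducibility: one master seed spawns per-iteration child seeds by
  drawing from a seeded integer stream, so iterations are independent and
  the full call table, null counts, and permutation p-values are
  bit-identical across runs.
* Boundary semantics follow the stated rules exactly: RIN strictly $>$,
  tissue minimum inclusive, log2FC strictly $>$, consistency bound
  inclusive.

## Problem sizes used in the shipped tests and scripts

The validation suite and `scripts/acceptance.R` run the sweep at 300–320
genes, 80 samples per sex, and 25 iterations for recovery checks (recall of
25-gene modules at $\rho_\mathrm{on} = 0.9$, false calls on 250 background
genes); null-calibration checks use 20 repeats at 100 genes, 40 samples per
sex, and 10 iterations/10 permutations per repeat; dominance checks use 5
planted repeats at 10/10. These sizes keep a full run in minutes on one CPU
while leaving the estimators in the regime where the planted effects are
clearly detectable. As noted above, percentile intervals from only 10
permutations cover at most ~82% nominally, so coverage summaries at that
scale read low even for a perfectly calibrated statistic; at the default 100
permutations the interval approaches its nominal 95%.

## Known limitations

* The tracked co-expression scalar is whole-network connectivity;
  module-restricted (intramodular) connectivity, topological overlap, and
  eigengenes are out of scope.
* The null interval inherits the discreteness and small-sample issues of any
  permutation percentile interval; use 100+ permutations for calibration
  claims.
* Direction consensus by majority vote can mask genes that genuinely flip
  direction between sample subsets; such genes surface as ties and warnings.
* No batch correction or covariate regression is applied; if the cohort
  confounds sex with a technical factor, the sweep will faithfully report
  the confounded signal.
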