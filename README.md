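# circscape

Downstream analysis of circular RNA (circRNA) expression across tissues
and developmental ages, in tidyverse-style R.

## The problem

Back-splicing joins a downstream splice donor to an upstream acceptor and
yields covalently closed circRNAs. Given per-sample back-splice junction
counts and paired circular/linear TPM tables per host gene (the outputs
of junction callers and model-based quantifiers), the questions this
package answers are the ones a multi-tissue, multi-age study design
poses:

* Which junctions constitute a reproducible circRNA repertoire, and where
  in the gene do they fall (exonic / intronic / intergenic)?
* How does circular expression relate to cognate linear expression, and
  what share of a gene's output — the circular fraction
  `TPM_circ / (TPM_circ + TPM_linear)` — is spliced into circles?
* Are circRNAs more tissue-specific than their host mRNAs? The tau index
  over `N` tissues, with `r_i` the tissue mean normalised to the maximum,
  is `TSI = Σ(1 − r_i) / (N − 1)` — 0 for uniform, 1 for single-tissue
  expression.
* Does circular expression track age, independently of the host gene? Per
  gene, Spearman's rho of expression versus age is computed for both
  layers; strongly correlated circRNAs (for example `rho > 0.7`) are
  compared with their linear counterparts by a one-tailed paired t-test,
  and the comparison is repeated over hundreds of random same-size gene
  sets (a resampling null for the "independence" claim).
* Which pathways do the responding circRNAs point to? Rank-weighted
  single-sample gene-set scores (weights `exp(−rank/N)`) plus Fisher
  exact enrichment with hypergeometric Z-scores.

Intended users are transcriptomics analysts who already have junction
counts and TPM matrices and want the downstream statistics, calls and
reports with a tested, reproducible implementation. A synthetic-data
generator with planted tissue-specific and age-dependent effects ships
with the package, so the whole pipeline runs — and is validated — without
any external data.

## Worked example

```r
library(circscape)
library(dplyr)

cfg <- sim_config(n_genes = 100, seed = 7)   # 11 tissues x ages 2/6/21/104 wk
sim <- simulate_dataset(cfg)

# repertoire: >= 1 junction read in >= 2 same-tissue samples
rep <- build_repertoire(sim$junction_counts, sim$metadata, sim$annotation)
nrow(rep)
#> [1] 100

# whole-tissue circular fraction trends upward with age in the brain
overall_fraction_trend(sim$expression, sim$metadata, "brain")
#> <circ_age_trend> brain: rho = 0.97, P = 5.24e-10 (n = 16, ok)

# per-gene age correlations, strict selection, resampling independence test
rho <- per_gene_age_correlation(sim$expression, sim$metadata, "brain")
sel <- select_age_sensitive(rho, "rho>0.7")
resampling_independence_test(rho, sel, n_resamples = 1000, seed = 42)
#> <circ_resampling_test> observed t = 16.445 (P = 2.18e-13, n = 21, greater)
#>   pass fraction: 1.000 over 1000 resamples (universe 100 genes)

# circular transcripts are more tissue-specific than their linear hosts
glance(paired_tsi_comparison(sim$expression, sim$metadata))
#> # A tibble: 1 x 6
#>   status statistic  p_value     n n_high_circ n_high_linear
#> 1 ok          5029 7.44e-18   100          30             0
```

The trend object says the overall circular fraction in brain rises almost
monotonically across the 16 brain samples (rho near the midrank maximum
for four tied age groups). The resampling test's observed t compares
circular against linear age correlations over the 21 selected genes; the
pass fraction of 1.0 means every random same-size gene set also showed
significantly higher circular rho — the planted tissue-wide circular age
drift, recovered. The TSI comparison counts 30 genes with circular
`TSI > 0.8` against 0 linear ones.

Every result object has `tidy()`/`glance()` accessors and most have
`autoplot()`/`plot_*()` views; `run_pipeline(cfg, outdir)` chains all
stages (simulate → repertoire → evolution → expression → specificity →
age → pathway) and writes TSV outputs plus a JSON manifest with checksums
and the seed. `inst/scripts/circscape` is a thin command-line wrapper.

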