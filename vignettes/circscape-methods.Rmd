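---
title: "circscape: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{circscape: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circscape)
library(dplyr)
```

## Scope and background

Circular RNAs (circRNAs) arise when pre-mRNA back-splicing joins a
downstream splice donor to an upstream acceptor, producing a covalently
closed transcript. Short-read RNA-seq detects them through reads spanning
the non-colinear back-splice junction; all isoforms sharing one junction
are collapsed into a single *circRNA species*. circscape implements the
downstream analysis of such data across a multi-tissue, multi-age design:

1. **Repertoire construction** from per-sample junction read counts, with a
   replication filter and annotation-based genomic classification.
2. **Conservation and lineage analysis** of exonic circRNAs.
3. **Circular-versus-linear expression relationships** per host gene.
4. **Tissue specificity** via the tau index, with tissue-specific calling,
   ordination and clustering views.
5. **Age dynamics** with per-gene rank correlations and a resampling
   independence test.
6. **Pathway-level scoring** (rank-weighted single-sample scores) and
   hypergeometric enrichment.

Upstream steps — junction discovery from raw reads and model-based TPM
estimation — are out of scope: their outputs (junction counts and paired
TPM tables) are this package's inputs. A synthetic-data generator with
planted effects stands in for them, so that every stage is testable
without downloads and so that detection rates can be measured against a
known truth.

## The synthetic-data generator

The generator emulates a body-wide rRNA-depleted RNA-seq design: by
default 11 tissues (including brain, testes and uterus) at ages 2, 6, 21
and 104 weeks, four replicates per tissue/age cell, with single-sex
reproductive tissues. Each of `n_genes` host genes carries exactly one
circRNA species; this matches an analysis conducted per host gene and
keeps truth bookkeeping unambiguous.

For gene $g$ and sample $s$ the model is built on the logit scale of the
circular fraction $f$:

$$
\log\frac{f_{gs}}{1-f_{gs}} = \beta_0
 + \beta_t\,[\text{tissue-specific gene in its planted tissue}]
 + a_{gs} + \eta_{gs},
$$

with per-gene linear abundance $L_g \sim \text{logNormal}(\mu,\sigma)$ and
observed layers

$$
\mathrm{TPM}^{\mathrm{lin}}_{gs} = L_g e^{\varepsilon_{gs}}, \qquad
\mathrm{TPM}^{\mathrm{circ}}_{gs} = e^{\mathrm{logodds}_{gs}}\,L_g ,
$$

where $\eta$ and $\varepsilon$ are independent Gaussians with a **common**
standard deviation (`noise_sd_logit`). The symmetry is deliberate: under
the null (no planted effects) the circular and linear layers are
exchangeable up to a constant shift, so paired circ-versus-linear
comparisons (TSI, age correlations, the resampling test) are exactly
calibrated — the package's null-calibration tests rely on this. When both
noise terms are zero, $\mathrm{TPM}_c/(\mathrm{TPM}_c+\mathrm{TPM}_l)$
recovers the generating fraction exactly.

Age enters as $\log(\text{weeks})$, because the design ages
(2, 6, 21, 104) are close to geometric — a linear-in-log-age effect then
translates into a near-linear rank trend. Two planted age profiles exist:

* **monotone** (`age_up`): slope `age_slope_logit` per log-week, planted
  in a designated brain-like tissue — circRNA accumulation with age;
* **rise-then-fall** (`age_up_down`): a tent in log-age peaking at the
  third age, planted in a testes-like tissue — an increase through sexual
  maturity followed by a decline in aged animals. The tent amplitude is
  scaled so its peak matches what the monotone slope reaches at the peak
  age, keeping the two profiles comparable.

A mild **tissue-wide drift** (`age_slope_global_logit`, default 0.1)
applies the same two shapes to *every* gene in those two tissues. This
mirrors the empirical situation that motivates the resampling test: the
whole circular transcriptome of the brain-like tissue trends upward with
age, not just a handful of genes, so random same-size gene sets also show
circular rho above linear rho. Setting it to 0 yields a global null.

Junction read counts are Poisson with mean
`mean_junction_depth * TPM_circ`; junction coordinates are exon runs of
the simulated annotation (all planted junctions are exonic — intronic and
intergenic classification is exercised by constructed fixtures in the test
suite instead). Auxiliary inputs include a per-base conservation track
(scores in $[0,1]$, with a +0.2 uplift inside circRNA spans), one-to-one
ortholog tables, foreign circRNA repertoires and a gene-set collection
containing the planted modules plus random decoys.

Default effect sizes (tissue boost 3 logits, age slope 0.5 per log-week,
noise SD 0.3, baseline logit −2 ≈ a 12% circular fraction) were chosen
once so that planted effects are strong but not degenerate — recovery
rates sit near, not at, their ceilings — and are used unchanged by the
validation suite.

What the generator does **not** emulate: read-level sampling noise shared
between the layers, multiple circRNA species per gene, isoform structure
within a junction, sex effects, batch structure, and any coupling between
host-gene expression level and splicing efficiency. Passing tests
therefore demonstrate correctness of the statistical machinery under the
stated model, not robustness to every property of real libraries.

## Repertoire rules

A junction enters the repertoire iff it has $\ge 1$ back-splice read in
$\ge 2$ distinct samples of the same tissue (ages and sexes pool within a
tissue). The filter is monotone: adding reads can only add species.

Classification is exact-boundary: a junction is *exonic* only when its
start coincides with an annotated exon start and its end with an exon end
of the same gene on the matching strand (0 bp tolerance — a deliberate,
conservative convention). Junctions overlapping a gene without boundary
matches are *intronic*; junctions touching no gene are *intergenic*. Ties
between overlapping genes go to the exon-boundary match first, then the
larger overlap, then the lexicographically first gene id — a deterministic
convention, since upstream tools do not document theirs. Coordinates are
0-based half-open internally and BED-style on disk; GTF annotation is
1-based inclusive.

## Statistics

**Tissue specificity (tau).** For per-tissue means
$x_1,\dots,x_N$ with $r_i = x_i/\max_j x_j$:
$$\mathrm{TSI} = \sum_{i=1}^{N}(1-r_i)\,/\,(N-1) \in [0,1],$$
0 for uniform expression, 1 for single-tissue expression; invariant to
positive rescaling and undefined for an all-zero gene. Tissue-specific
circRNAs are called at `TSI >= 0.8` with peak mean TPM of at least 1 —
the 0.8 cut echoes the conventional high-specificity threshold, and the
expression floor prevents calls driven by near-zero noise; both are
package conventions, exposed as arguments.

**Rank correlations.** All trend statistics are Spearman's rho computed
as Pearson on midranks; tied regressors (four replicates per age) are
handled by midranks, which caps the attainable rho below 1 — tests verify
equality with an independent midrank oracle to 1e-12. P-values use the
asymptotic approximation (ties make the exact null unavailable). An
exactly constant response is reported as rho 0 with P 1 by convention
rather than NA: "no trend" is the scientifically meaningful summary of a
flat profile; `spearman_rho()` itself stays strict and returns NA.

**Age-sensitive selection and the resampling test.** Genes pass a strict
threshold rule on the circular-layer rho (`rho>0.7` excludes 0.7 itself,
matching the printed inequality). The independence question — is the
circular age trend just inherited from the host gene? — is addressed by a
one-tailed paired t-test of circular versus linear rho on the selected
set, repeated on `n_resamples` uniformly drawn same-size sets from the
universe of genes with defined rho in both layers. When both layers are
identical the paired t statistic is defined as 0 with P 1 (the textbook
statistic is 0/0). Stage windows (all ages, 2–21 wk, 21–104 wk) restrict
which samples enter the correlation, so a rise-then-fall profile splits
into a positive rising-window rho and a negative falling-window rho.

**Conservation by codon position.** Per exonic circRNA, the CDS of the
host gene's longest transcript is walked in coding order (reverse
coordinate order on the minus strand), assigning codon positions 1/2/3;
per-base conservation scores are averaged separately over bases inside the
circRNA span and bases exclusive to the linear transcript, and the two
groups of per-circRNA means are compared per position with a
Kolmogorov–Smirnov test. Genes without CDS are excluded; circRNAs that
cover the entire CDS have no linear-only bases and contribute NaN to that
side.

**Lineage.** Orthology is resolved at the host-gene level: a circRNA is
mammalian-common when one-to-one human *and* mouse orthologs both carry a
circRNA in the foreign repertoires, rodent-specific when only the mouse
ortholog does, rat-specific otherwise. Junction-coordinate liftover is
deliberately not attempted — gene-level matching is the reproducible
reading of repertoire-to-repertoire comparison, and the foreign
repertoires arrive as plain gene lists.

**Pathway scores.** The single-sample score ranks genes by descending
expression (midranks on ties) and weights each gene
$w_g = e^{-\mathrm{rank}_g/N}$; the score is the mean weight over the set
minus the mean weight over its complement. The exponential kernel is a
declared choice: it reproduces the defining properties of rank-weighted
scoring — zero under uniform expression, maximal for the top-$k$ set,
invariant under monotone transforms — and swapping set and complement
negates the score exactly. Enrichment uses the two-sided Fisher exact
test plus the hypergeometric Z-score
$Z = (k - nK/N)\,/\,\sqrt{nK(N-K)(N-n)/(N^2(N-1))}$; terms rank by Z,
then P, then name (alphabetical tie-break), with Benjamini–Hochberg
q-values reported alongside raw P for responsible reuse. The enrichment
universe is the set of genes analysed in the relevant tissue, so the
background matches the selection pool.

**Ordination.** PCA and Ward clustering (`ward.D2`, Euclidean) operate on
`log2(TPM + 1)` — a variance-stabilising convention. Cluster purity is
the share of samples whose cluster's majority tissue is their own.

## Numerical conventions and degenerate inputs

* Circular fraction of a (0, 0) gene/sample: undefined, excluded.
* All-zero expression vectors: TSI undefined (NA), gene excluded.
* Constant layers: correlation NA from `spearman_rho()`; trend wrappers
  report rho 0 / P 1 only when the response is constant to within
  floating-point rounding.
* Paired tests with fewer than 2 genes, or all-zero differences, return an
  explicit `status` instead of a P-value.
* Junctions on chromosomes absent from the annotation classify as
  intergenic with a warning.
* One global seed drives everything; generator stages use fixed offsets
  from it so a stage rerun alone reproduces its slice.

## Validation scale

The packaged validation suite measures null calibration over 200
simulated datasets of 200 genes (11 tissues × 4 ages × 4 replicates),
planted-effect recovery on single datasets of 120–200 genes, the
repertoire filter against brute force on 1000 random toy tables, and the
Fisher P against exhaustive hypergeometric tail summation for every table
with a universe up to 20 plus randomized tables up to 50. These sizes are
the package's chosen trade-off between statistical resolution (binomial
error on a 5% rate over 200 × 50 resamples is well inside the tested
band) and a test suite that runs in minutes.

## Known limitations

* The exonic/intronic/intergenic split of simulated data is degenerate
  (all planted junctions are exonic); classification breadth is covered by
  constructed fixtures rather than the generator.
* The pathway stage uses ordinal age stages of the testes-like tissue as
  its staging axis; a dedicated spermatogenic-cell dataset would use cell
  types instead — the machinery is identical.
* Fisher/Z enrichment treats gene sets as flat lists; no ontology
  structure, term redundancy trimming or propagation is attempted.
* P-values for rank correlations are asymptotic; at very small n (single
  samples per stage) prefer the enumerable rho itself.

## A minimal run

```{r, eval = FALSE}
cfg <- sim_config(n_genes = 100, seed = 7)
out <- run_pipeline(cfg, tempfile("circscape"), n_resamples = 200)
names(out$stages)
```
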