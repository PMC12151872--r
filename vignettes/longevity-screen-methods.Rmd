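---
title: "Methods: the weighted longevity screen and transcriptome stratification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the weighted longevity screen and transcriptome stratification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(longescreen)
```

This vignette is the package's own account of the statistics it
implements: the models, the defaults and why, what the synthetic data
do and do not emulate, and the places where a design choice was
genuinely open.

## 1. The weighted gene–lifespan screen

### Model

Essential genes cannot be assayed by deletion, but their expression
varies across viable knockout strains. The screen treats each gene $j$
separately and fits, across strains $i = 1, \dots, M$,

$$ \min_{\beta_0, \beta_{1j}} \; \sum_{i=1}^{M} w_i
   \left( y_i - \beta_0 - \beta_{1j} x_{ij} \right)^2 $$

with $y_i$ the percent lifespan change of strain $i$ relative to wild
type, $x_{ij}$ the expression log2 fold change of gene $j$ in strain
$i$, and

$$ w_i = \frac{n_i}{n_i + 50} $$

where $n_i$ is the number of cells dissected in strain $i$'s
replicative-lifespan assay. A strain measured on many cells approaches
weight 1; a strain with a handful of cells contributes little. The
offset 50 is exposed (`offset` argument) but is part of the stated
method, not a tuning knob.

### Inference (an open design point)

The cost function defines the estimator but not a standard error. We
adopt the standard precision-weight convention:
$\hat\sigma^2 = \mathrm{RSS}_w / (M - 2)$,
$\widehat{\mathrm{Var}}(\hat\beta_1) = \hat\sigma^2 / \sum_i w_i (x_i -
\bar x_w)^2$, two-sided $t$ with $M - 2$ df. Two facts recommend this
choice: the whole inference is invariant to rescaling all weights by a
positive constant (only relative reliability can matter, since the
weights are dimensionless), and if the residual variance truly is
proportional to $1/w_i$, the $t$ statistic is exactly calibrated —
which the generator makes true by construction (Section 4) and the
null-calibration tests confirm.

Genes are ranked by raw p-value of the slope; Benjamini–Hochberg
q-values are reported alongside but do not drive the ranking. Ties are
broken by larger $|\hat\beta_1|$, then lexicographic gene id, so output
is deterministic. Numerically, $x$ is centred at its weighted mean
before solving the normal equations.

Missing expression values are handled per gene (complete-case); genes
with fewer than `min_strains` (default 10) usable strains are reported
in a `skipped` table rather than silently dropped. We screen every gene
supplied rather than pre-filtering to essential genes — essentiality is
a property of the interpretation, not of the regression — so callers
can subset either before or after.

## 2. Lifespan-assay statistics

Cohort means are taken over observed (uncensored) lifespans; `n` is the
full cohort size. Percent extension is $100 (m_T - m_C)/m_C$, reported
in headline form rounded to one decimal. Kaplan–Meier estimation and
the two-group log-rank test are delegated to the `survival` package
(product-limit estimator; hypergeometric-variance log-rank without
continuity correction). Censoring handling is our addition — the
assays this emulates rarely discuss it, but worm assays lose animals —
and is exercised properly by KM/log-rank while means simply exclude
censored records.

Dose–response smoothing uses LOESS with degree 1, tricube weights, span
0.75 and no robustness iterations (`stats::loess` with
`surface = "direct"`, which we verified equals an independently coded
tricube local-linear smoother with $q = \lfloor \mathrm{span} \cdot n
\rfloor$ neighbours to machine precision). Local-linear fits reproduce
straight lines exactly, which the tests use as an identity check. The
span default is stated once and not adjusted per dataset.

## 3. DEG calling and stratification

A gene is a DEG when $|\log_2 \mathrm{FC}| > 1$ and BH-adjusted
$p < 0.05$. The differential-expression engine itself is deliberately
pluggable: precomputed per-gene tables (`read_deg_stats()`) are
authoritative when supplied; otherwise a Welch $t$ test on
$\log_2(\mathrm{FPKM} + 1)$ across replicates is the documented
fallback. The $+1$ stabilises low-abundance genes at the cost of
attenuating their fold changes — one reason the generator plants
effects in quantifiable genes (Section 4).

Stratification analyses:

* **Promoter state.** Each gene carries an `active`/`inactive`
  promoter label, either given directly or derived from BED
  chromatin-state segments overlapping a TSS ± 1 kb window (BED is
  0-based half-open, TSS tables 1-based; a gene is active if *any*
  overlapping segment is active). The window is symmetric, so strand
  affects bookkeeping only. Association between DEG direction and
  promoter state uses the Pearson 2×2 chi-square (closed form, no
  continuity correction — the convention chosen here and stated, since
  none was specified). Zero-margin tables return proportions with an
  `NA` statistic rather than failing.
* **Abundance bins.** Genes are binned by total control FPKM (sum over
  control replicates — our reading of "total FPKM in the control
  group"). The extremely-high class is strictly `> 5000`; 5000 exactly
  is `high`. The two inner edges default to the 25th/75th percentiles
  of the sub-5000 totals: three bins need two edges, and quartile edges
  make "low" and "high" symmetric tails of the sub-threshold
  distribution. Both edges are configurable.
* **Shared DEGs.** Exact Venn tables per direction: for every tissue
  subset, the genes differential in at least those tissues and the
  exclusive region counts, which partition the union (a tested
  invariant).
* **Enrichment.** One-sided Fisher exact per term from the
  hypergeometric tail (`phyper`), BH across terms, sorted by p. The
  one-sided choice matches the enrichment question being asked.

## 4. What the synthetic data emulate — and what they do not

`simulate_screen_dataset()` draws $x_{ij} \sim N(0,1)$, lifespans
$y_i = \sum_{j \in \mathrm{drivers}} \beta_j x_{ij} + \varepsilon_i$
with $\varepsilon_i \sim N(0, \sigma^2 (n_i + 50)/n_i)$ and cell counts
uniform on 10–200. The noise law is chosen *so that* the screen's
weight formula is the exact inverse-variance weight — that is the
generator's rationale, making the stated method optimal in its own
world, not a claim about any real assay. Defaults (driver slopes 3–8
percent per unit log2FC, $\sigma = 5$ percent) were fixed once as
plausible scales for replicative-lifespan variation and are not
adjusted against test outcomes.

`simulate_lifespan_cohort()` uses a Gompertz lifetime distribution (the
standard demographic ageing model): shape $b = 1/(\delta m)$ for target
mean $m$ and dispersion $\delta$ (default 0.12, giving a coefficient of
variation around 0.15, typical of laboratory cohorts), with the
baseline hazard solved numerically so the distributional mean equals
the target, and sampling by the closed-form inverse CDF. Censoring is
independent: with probability `censor_frac` a record is cut at a
uniform point before its death time.

`simulate_expression_experiment()` draws baseline FPKM log-normal
(meanlog 3, sdlog 2 — heavy-tailed enough that a 4-replicate control
total clears 5000 for roughly the top 2% of genes), multiplies
treatment means by $2^{\mathrm{lfc}}$ for planted DEGs, and applies
mean-preserving multiplicative log-normal replicate noise (sdlog 0.2,
i.e. ~20% CV). Planted genes are drawn from genes with baseline ≥ 5
FPKM so their effects survive the $\log_2(x+1)$ transform; optional
abundance-bias exponents concentrate down-regulation among abundant
genes to emulate selective repression of highly expressed genes; one
planted down gene is lifted into the extremely-high class by default.
Promoter states are Bernoulli with active-probability increasing in
log-abundance and boosted for planted-down genes; one annotation term
is planted enriched in the down set (30 genes, 20 of them planted
down).

Not emulated: read-level sequencing noise, normalisation artefacts,
batch effects, correlated genes, tissue heterogeneity, and real
chromatin annotation. A green test therefore establishes that the
*statistics* recover planted structure at realistic scales — not that
any biological conclusion transfers.

All generators are deterministic functions of their `seed`
(Mersenne-Twister via `set.seed`), and every planted effect is
recorded in a `truth` object that round-trips without rerunning the
generator.

## 5. Numerical choices and degenerate inputs

* Perfect fits: constant $y$ gives slope 0, $t = 0$, $p = 1$; an exact
  non-zero-slope line gives $p = 0$. Constant $x$ is a degenerate
  design and errors.
* Welch test with two zero-variance groups: $p = 1$ if the means agree,
  else $p \to 0$; implemented explicitly rather than left to chance.
* 2×2 chi-square computed in double precision (the margin product
  overflows 32-bit integers around counts of a few hundred).
* Classed conditions (`longescreen_input_error`,
  `longescreen_degenerate_error`, `longescreen_insufficient_data_error`,
  `longescreen_config_error`, `longescreen_schema_error`,
  `longescreen_join_error`) let callers and tests react without
  string-matching messages.
* File errors name the file, 1-based line and column.

## 6. The pipeline

`run_pipeline()` chains simulate → screen, cohorts → survival +
dose–response, and per-tissue experiments → DEGs → stratification →
enrichment from a single validated `pipeline_config()`. Per-stage
seeds are derived as `seed + k` so the whole run is reproducible;
`manifest.json` records versions, seeds, thresholds and counts but
deliberately no timestamps, so identical configurations produce
byte-identical output trees. The multi-tissue stage pins a subset of
planted down-regulated genes to be shared across tissues, emulating a
conserved down-regulation signature against tissue-specific
up-regulation.

## 7. Known limitations

* The screen is single-gene: no joint or regularised modelling, and no
  causal interpretation — a driver's estimated slope absorbs sample
  correlation with other drivers (exact recovery holds only in the
  single-driver noiseless limit).
* The Welch fallback is not a negative-binomial count model; for real
  RNA-seq, supply a dedicated DE caller's table.
* Promoter labelling from BED segments uses a fixed ±1 kb window and
  any-active precedence; real promoter definitions are richer.
* LOESS extrapolation beyond the dose range is not supported (the grid
  stays within the observed range).
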