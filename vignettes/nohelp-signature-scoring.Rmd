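---
title: "Deriving and scoring a helpless CD8 T cell signature"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving and scoring a helpless CD8 T cell signature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nohelpscore)
```

`nohelpscore` packages a three-stage transcriptomic workflow: derive a
two-condition differential-expression signature from bulk RNA-seq counts,
place query transcriptomes on the axis between the two conditions with a
nearest-centroid correlation score, and characterize the contrast with
gene-set enrichment analysis and standard group statistics. The motivating
biology is CD8+ T cell "helplessness": cells primed without CD4+ T cell
help express a program resembling the predysfunctional TCF-1+ state of
chronic infection and tumors, and the score quantifies how helpless-like
any given population looks. This vignette explains the models, the
parameters that matter, the design decisions taken where the design was
genuinely open, and what the synthetic-data tests do and do not establish.

## The differential-expression model

Counts for gene $g$ in sample $i$ are modeled as negative binomial with
mean $\mu_{gi}$ and a single common dispersion $\varphi$, so that
$\mathrm{Var} = \mu + \varphi\mu^2$ and $\varphi = 0$ recovers the Poisson.
A common dispersion is a deliberate simplification: with three replicates
per condition there is very little information for per-gene (tagwise)
dispersion, and the packaged pipeline favors a small, fully auditable
estimator over shrinkage machinery. Consequently we do not expect to
reproduce any particular published gene list exactly; the target is a
well-calibrated test with the same structure.

**Putting samples on a common scale.** Before testing, counts are divided
by their per-sample effective library size (column sums, optionally times a
TMM factor), multiplied by the geometric mean of those sizes, and rounded
half-up to integers. Deterministic half-up rounding keeps the exact-test
enumeration on integers and makes runs reproducible across platforms; the
quantile-based refinement used by some established DE tools is intentionally
out of scope. The cost of rounding is a small distortion when library sizes
are very unequal — with sizes within a factor of two (the simulated range),
its effect on p-values is below the discreteness of the test itself.

**Dispersion estimation.** $\varphi$ maximizes the *conditional*
log-likelihood of the within-group pseudo-counts given each gene's group
total, summed over genes, searched on a log-spaced 21-point grid on
$[10^{-4}, 5]$ and refined by golden-section search (log-scale tolerance
$10^{-4}$). The conditional likelihood matters: the unconditional ML with a
free mean per gene underestimates $\varphi$ by roughly 40% at three
replicates per group (the means absorb one degree of freedom per gene per
group), which in turn makes the exact test anti-conservative — we measured
a null $p<0.05$ fraction of 0.09 with the unconditional estimator against
0.04–0.05 with the conditional one at true $\varphi = 0.1$. Conditioning on
the totals removes the means from the likelihood entirely, and is the same
conditioning the exact test itself relies on.

**The exact test.** Conditional on a gene's total pseudo-count $T$, the
split between group sums follows a negative hypergeometric law that depends
only on the group sizes and $\varphi$, not on the unknown mean. The
two-sided p-value is the summed probability of all splits no more likely
than the observed one; ties are included with a relative tolerance of
$10^{-12}$ so floating-point noise can never exclude the observed split.
A zero total gives $p = 1$ by convention. At $\varphi = 0$ the law reduces
to binomial and the test to the exact binomial test — one of the oracle
checks in the suite.

**FDR and the signature.** Benjamini–Hochberg q-values (via
`stats::p.adjust`) are thresholded at $q < 0.01$. Log2 fold changes are
computed from CPM group means with a 0.5 offset to avoid infinities, and
the signature is ordered by $q$ ascending, then $|\log_2\mathrm{FC}|$
descending, then gene id — fully deterministic.

## The No Help score

For each reference condition the centroid is the per-gene arithmetic mean
of normalized expression across replicates, restricted to the signature
genes present in the reference. A query profile's score is the Pearson
correlation with the No-Help centroid minus the correlation with the Help
centroid, both computed on the identical overlap gene set, so the score
lives in $[-2, 2]$ and inherits Pearson's invariance to shifting and
positive rescaling of the query.

Two defaults deserve comment:

* **Untransformed CPM.** Correlations are computed on plain CPM by
  default. Correlation on raw CPM is dominated by high-expression genes; a
  `log2_offset` option exists in `cpm()` for users who prefer a
  variance-compressed scale, but the default keeps the score on the
  unlogged normalized counts the method was defined on. Whatever the
  choice, reference and query must be normalized identically.
* **Minimum overlap of 10 genes.** Correlations over fewer genes are
  statistically meaningless; scoring stops with an error below the
  threshold rather than returning a fragile number. The value is a
  configurable floor, not a tuned constant.

Cross-species scoring uses a two-column mapping table filtered to pairs
that are one-to-one in both directions; ambiguous pairs are dropped and
counted. When no table is supplied, matching falls back to exact string
equality after uppercasing, which handles the common mouse/human symbol
case difference (`Tcf7` vs `TCF7`) without silent failure.

## GSEA

Genes are ranked by the signal-to-noise metric
$(\bar{x}_A - \bar{x}_B)/(s_A + s_B)$ with each group's standard deviation
floored at $\max(0.2\,|\bar{x}|, 10^{-8})$ — the conventional floor that
stops near-constant genes from dominating the ranking. Ties are broken
lexicographically by gene id so the ranking is identical across platforms.
The enrichment score is the extremum of the weighted running sum (hit
increments $|m|^p$-normalized, miss decrements $1/(N-N_{hit})$), with
$p = 1$ by default and $p = 0$ exposed for the classical unweighted
statistic.

The permutation null defaults to same-size random gene sets rather than
label permutation because the motivating designs have three samples per
arm, where label permutation supports only $\binom{6}{3} = 20$ distinct
splits; phenotype mode exists and switches to exhaustive enumeration
whenever the number of splits is at most 10,000. The p-value uses the +1
pseudo-count convention over same-sign nulls, and NES divides the observed
ES by the mean |null ES| of the same sign. If no same-sign null appears,
p is floored at $1/(1+n_{perm})$ with a warning rather than reported as 0.

## Group statistics

Unpaired comparisons use the classical pooled-variance Student's t-test
(not Welch — the pooled form is what "Student's t-test" names). Matched
designs use within-subject one-way ANOVA with the subject-by-condition
interaction as the error term, and Tukey pairwise p-values from the
studentized-range distribution; tail probabilities come from
`stats::ptukey`'s numerical integration, validated in the test suite
against a Monte-Carlo studentized-range oracle. Degenerate inputs are
handled explicitly: identical groups give $t = 0, p = 1$; a flat matched
table gives $F = 0$; zero error variance with a real condition effect is an
error rather than an infinite statistic.

## What the synthetic data emulates

`simulate_reference()` draws per-gene baseline means from a log-normal
(meanlog 5, sdlog 1.5 on the natural-log scale — a realistic spread of
four-plus orders of magnitude for a bulk panel), applies the configured
fold change to half of the DE genes upward and half downward in the NoHelp
condition, and draws NB counts with expected value proportion × library
size, library sizes uniform on $[3\times10^5, 6\times10^5]$. The defaults —
2,000 genes, 3 vs 3, 10% DE at $|\log_2\mathrm{FC}| = 2$, $\varphi = 0.1$,
seed 17 — define the fixture all end-to-end tests run on; 2,000 genes keeps
the exact-test enumeration comfortably fast while leaving ~1,800 true nulls
for FDR behavior to be measurable. The type-I-error simulation uses 5,000
genes for a tighter estimate of the rejection fraction.

`simulate_query()` builds query samples as $w\cdot c_{NoHelp} +
(1-w)\cdot c_{Help}$ plus gene-wise Gaussian noise with standard deviation
proportional to the gene's centroid magnitude, floored at zero.
Multiplicative-scale noise preserves the correlation structure that the
score depends on while keeping expression non-negative; $w$ is the known
ground truth that score monotonicity is tested against.

What passing these tests shows: the exact test is calibrated under its own
generative model, the signature recovers planted effects, and the score
ranks populations by their true mixture weight under centroid-mixture
queries. What it does not show: robustness to batch effects, to
compositional distortions between datasets, to gene-length or GC biases,
or to real cross-species ortholog structure — the generator makes no
attempt to mimic real LCMV/tumor biology or actual gene symbols, and
results on real data depend on upstream processing choices the package
does not control.

## Numerical choices, at a glance

* Exact-test tie tolerance $10^{-12}$ (relative); p clipped to $(0, 1]$.
* Dispersion search grid $[10^{-4}, 5]$, 21 log-spaced points,
  golden-section refinement to $10^{-4}$ on the log scale.
* TMM: per-tail trims of 30% (M values) and 5% (A values), precision
  weights from the delta-method variance, factors rescaled to geometric
  mean 1; factors within $10^{-6}$ of 0 on the log2 scale snap to exactly 1.
  TMM is exposed everywhere but applied by default only where a
  between-sample scaling step is explicitly requested; the scoring path
  uses plain CPM.
* log2 fold change offset 0.5 on CPM means.
* All generators and permutation tests consume explicit seeds and restore
  the caller's RNG state.

## Known limitations

The DE stage fits one dispersion for all genes; genes with unusually high
biological variability will be anti-conservative relative to a tagwise
model. The exact test enumerates all splits of each gene's total, which is
exact but scales linearly with sequencing depth; for very deep libraries a
saddlepoint or normal approximation would be the natural extension. The
score is a difference of correlations and therefore insensitive to overall
expression magnitude — by design, but it means two populations can share a
score while differing biologically in scale. GSEA reports no across-set
FDR; when testing many sets, adjust the reported p-values externally.
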