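# nohelpscore

CD8+ T cells primed without CD4+ T cell help ("helpless" cells) acquire a
distinctive transcriptional program that resembles the predysfunctional
TCF-1+ state seen in chronic infection and cancer. A practical way to ask
whether some population of interest looks "helpless" is to (1) derive a
**No Help signature** — the genes differentially expressed between
non-helped and helped antigen-specific CD8+ T cells — and (2) place any
query transcriptome on a helped-to-helpless axis with a **No Help score**.
`nohelpscore` implements that workflow end-to-end for bulk RNA-seq count
matrices, together with the gene-set enrichment analysis and group
statistics that accompany it, and a seeded synthetic-data generator so the
whole pipeline is testable with known ground truth and no external
downloads.

## The methods

**Signature derivation.** Counts are modeled as negative binomial with a
single common dispersion φ (variance = μ + φμ²), estimated by maximizing
the conditional likelihood of within-group counts given each gene's group
total on a log-spaced grid refined by golden-section search. Each gene is
tested with a conditional exact test: samples are scaled to the common
effective library size, summed per group, and the two-sided p-value sums
the conditional probabilities of all splits of the total no more likely
than the observed one (at φ = 0 this is the exact binomial test).
Benjamini–Hochberg FDR control at q < 0.01 yields the signature.

**No Help score.** For the two reference conditions, per-gene centroids are
the mean CPM over replicates, restricted to the signature genes. A query
profile's score is

    score(x) = r(x, centroid_NoHelp) − r(x, centroid_Help)

with `r` the Pearson correlation over the common gene set. Higher scores
mean greater transcriptional similarity to helpless cells. A one-to-one
gene-id mapping table supports cross-species scoring.

**GSEA.** Genes are ranked by the signal-to-noise contrast
(mean_A − mean_B)/(sd_A + sd_B); a gene set's enrichment score is the
extremum of the weighted Kolmogorov–Smirnov-like running sum; significance
and NES come from a same-size random-set permutation null (an exhaustive
label-permutation mode is available for small designs).

**Group statistics.** Pooled-variance Student's t-test for unpaired
comparisons; repeated-measures one-way ANOVA with Tukey contrasts
(studentized-range tail probabilities) for matched designs.

## Worked example

The numbered scripts under `analysis/` run the whole study on the default
synthetic fixture (2,000 genes, 3 vs 3 replicates, 10% DE at |log2FC| = 2,
φ = 0.1, seed 17):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_derive_signature.R
Rscript analysis/03_score.R
Rscript analysis/04_gsea.R
Rscript analysis/05_compare.R
```

which prints, among other things:

```
Signature: 161 genes at FDR < 0.01 (common dispersion 0.099).
Against the simulation truth: sensitivity 0.81, false-discovery proportion 0.000.

Reference self-scores: NoHelp mean +0.344, Help mean -0.330 (signature genes used: 161).
Query panel mean score by mixture level:
 group no_help_score
  w000   -0.33795433
  w025   -0.04573475
  w050    0.16597883
  w075    0.28076775
  w100    0.35374764

true_up_in_NoHelp: ES +0.985, NES +3.81, p = 0.003058 (100 genes in list, leading edge 100).
true_down_in_NoHelp: ES -0.922, NES -3.36, p = 0.001481 (100 genes in list, leading edge 88).

Extreme panels (w100 vs w000): t = 27.58 on 6 df, p = 1.5e-07.
Across all mixture levels: F(4, 12) = 517.82, p = 2.54e-13.
```

Reading this: the derived signature recovers 81% of the truly DE genes with
no false discoveries; the reference conditions score on opposite sides of
zero; query panels built as graded mixtures of the two centroids score
monotonically in their true mixing weight; the true up-regulated set is
strongly enriched at the top of the No-Help-vs-Help ranking (NES > 0) and
the down-set at the bottom (NES < 0). Intermediate tables land under
`results/`.

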