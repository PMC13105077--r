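# haplodomain

Analysis pipeline for the effects of humanized Klotho (*KL*) haplotypes on
the brain transcriptome — and, generally, for any design in which a
three-level ordered genotype grouping (here FC < WT < VS carriers) is
tested against gene-level counts, curated gene-set collections, and
exon-level usage.

It is written for transcriptomics analysts who have: a gene × sample count
matrix with metadata (genotype at two engineered loci, sex, age cohort,
sequencing batch), exon/transcript count blocks per gene, gene-set
collections (an AD Biodomain-style domain/subdomain hierarchy and KEGG-style
pathways in GMT), an ortholog table, and optionally a two-group
(treated/untreated) expression experiment to compare effect sizes against.
A synthetic-data generator with known ground truth replaces the original
animal data, so the whole pipeline is testable end to end.

## What it computes

* **Normalization** — median-of-ratios size factors; `log2(count/sf + 1)`
  variance-stabilizing transform; exact least-squares removal of sequencing
  batch, then sex; marker-based sex validation (Xist / Eif2s3y / Ddx3y).
* **Per-gene factorial model** —
  `y = β1 age + β2 sex + β3 haplotype + β12 + β13 + β23 + ε`,
  per-term partial F-tests respecting marginality, BH within term, DEG
  counts per term and cohort; dominant-vs-additive genotype-coding
  comparison by adjusted R².
* **Gene-set trend model** — per-sample set means; ordered-haplotype
  regression `y = β1 haplotype + ε` with the centered linear contrast
  (−1, 0, +1), adjusted R² as effect strength (sign of β: positive = higher
  in VS carriers); BH screening per family (subdomains at FDR 0.05,
  KEGG × Biodomain intersections of ≥ 10 genes at FDR 0.001); effect-sorted
  tables and the pathway × domain biadjacency matrix.
* **Differential exon usage** — Dirichlet-multinomial regression with
  logit-linear proportions over intercept + batch + sex + genotype,
  FC-vs-VS likelihood-ratio tests with a small-sample Bartlett-type
  correction, features pre-filtered to those expressed in ≥ 10 samples with
  mean ≥ 10 reads, significance at adjusted p ≤ 0.05.
* **Cross-system concordance** — set-level treatment coefficients in a
  two-group experiment via one-to-one orthologs and replicate-averaged
  group means, compared with the mouse β's by Spearman rank correlation and
  per-set concordant/discordant/null calls.

## Worked example

The end-to-end driver runs every stage on synthetic data with eight planted
intersection-level haplotype effects (|δ| = 2 SD, 12-month cohort only) and
four planted exon-usage shifts:

```r
library(haplodomain)
cfg <- default_config(seed = 1, out_dir = "run1")
man <- run_pipeline(cfg)
unlist(man$deg_counts)
#>           age           sex     haplotype       age:sex age:haplotype sex:haplotype
#>             0             3             1             0             0             0
man$n_significant_intersections
#> [1] 9
man$dtu_significant
#> [1] 4
round(man$cross_system_rho, 3)
#> [1] 0.714
```

Read: the genome-wide per-gene scan finds essentially nothing (the planted
effects are set-level, each gene's shift is far below per-gene power —
one haplotype DEG, interactions at zero), while the intersection trend
model recovers the planted sets (9 significant at FDR ≤ 0.001, including
all 8 planted), the usage test recovers all 4 planted splicing shifts, and
the organoid-style comparison returns a strongly positive rank correlation
for effects generated concordantly. Stage tables (`samples.tsv`,
`counts.tsv`, `expression.tsv`, `term_stats.tsv`, `deg_counts.tsv`,
`intersection_trend.tsv`, `biadjacency.tsv`, `dtu_results.tsv`,
`cross_system.tsv`) and a `manifest.yaml` with parameters, output checksums
and warnings are written under `out_dir`; identical config + seed
reproduces identical checksums.

For real data, skip the simulate stage and use the readers
(`read_counts()`, `read_samples()`, `read_gmt()`, `read_exon_counts()`,
`read_orthologs()`) with the stage functions directly; the methods
vignette (`vignettes/haplotype-geneset-methods.Rmd`) documents every model,
default and numerical choice.

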