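# muscleMeta

Dual-statistic differential-expression calling and cross-study
meta-analysis for case/control muscle transcriptome studies, with a
fully specified synthetic-data generator for end-to-end verification.

## The problem

Two chronic atrophying conditions of skeletal muscle — Duchenne
muscular dystrophy (DMD) and age-related sarcopenia (AGE) — are
profiled against a shared control group on small microarray cohorts.
Three questions follow: which genes are differentially expressed in
each condition; which of those calls replicate across independent
public datasets; and whether the replicated signatures are biased
toward particular functional gene sets or transcription-factor targets.
muscleMeta implements that workflow for analysts who have expression
matrices with sample annotations (condition, cohort, sex, dataset,
replicate array), probe-to-gene maps and GMT gene-set collections.

## Core statistics

* **Pooled two-sample t** per gene,
  `t = (x̄₁ − x̄₂) / (s·√(1/n₁ + 1/n₂))`, also used to call ternary
  status `+`/`−`/`0` versus pooled controls at raw p < 0.01 on merged
  meta-matrices.
* **SAM-style relative difference** `d = (x̄₁ − x̄₂)/(se + s₀)` with the
  fudge constant `s₀` chosen to stabilise the coefficient of variation
  of |d| across standard-error bins, and FDR `q` estimated from
  balanced label permutations (median permuted exceedance count over
  observed count, running minimum over thresholds).
* **Empirical-Bayes moderated t**: gene variances shrunk toward a
  scaled inverse-chi-square prior `(d₀, s₀²)` fitted by moment matching
  of `log s²` with digamma/trigamma identities;
  `s̃² = (d₀s₀² + d·s²)/(d₀ + d)`, t referred to `d₀ + d` df.
* **Intersection rule**: a gene is a DEG iff SAM FDR < 0.02 **and**
  moderated-t p < 0.01 (signs must agree); DMD/AGE lists are
  partitioned into condition-specific, shared-consistent and
  shared-inconsistent classes with a conservation audit.
* **Meta-clusters**: the (DMD status, AGE status) pair places each gene
  in one of nine grid cells (`DMD+AGE+` … `DMD0AGE0`); in-lab calls are
  validated, contradicted or unconfirmed against them, and the same
  t-test strategy on control samples screens for sex-biased genes.
* **Direction-aware set bias**: both hypergeometric tails
  `P(X ≥ k)`, `P(X ≤ k)` per (cluster, set) pair against the
  expressed-gene universe; candidate TFs need an enriched binding-site
  set *and* differential expression of the TF gene itself.

## Worked example

The generator emulates the full study design — quadruplicate spots,
duplicate arrays per subject, multi-dataset compendia with shared
ground truth — so the entire pipeline runs in seconds:

```r
library(muscleMeta)
cfg <- syntheticConfig(nGenes = 600, nDatasets = 3, nSets = 12, seed = 11)
res <- runSyntheticPipeline(cfg, nPerm = 200)

attr(res$partition, "counts")
#>            DMD_only_up          DMD_only_down            AGE_only_up
#>                     15                     15                     19
#>          AGE_only_down   shared_consistent_up shared_consistent_down
#>                     15                     12                     15
#>    shared_inconsistent
#>                     29

attr(res$metaClusters, "counts")
#> DMD+AGE+ DMD+AGE- DMD+AGE0 DMD-AGE+ DMD-AGE- DMD-AGE0 DMD0AGE+ DMD0AGE-
#>       15       15       18       15       16       17       18       18
#> DMD0AGE0
#>      468

sum(res$validation$validated_any)   # in-lab DEGs confirmed by the compendium
#> [1] 120
sum(res$sexBias$sex_biased)
#> [1] 26
```

The partition counts are the in-lab intersection calls (the generator
planted 2-SD effects on 2.5% of genes per non-null cell, i.e. 15 per
cell); the meta-cluster table shows the compendium assigning genes to
the nine status-pair cells, whose sizes sum to the 600-gene universe.
All 120 in-lab DEGs are validated by the three-dataset compendium at
these effect sizes.  Planted gene-set enrichments surface with
hypergeometric tail probabilities around `1e-11`:

```r
enr <- res$enrichment
head(enr[enr$verdict == "ENRICHED",
         c("set_name", "cluster", "k", "K", "n", "p_over")])
#>  set_name  cluster  k  K  n       p_over
#>    set003 DMD+AGE0 12 40 18 1.944993e-11
#>    set004 DMD-AGE+ 11 40 15 3.164022e-11
#>    set001 DMD+AGE+ 11 40 15 3.164022e-11
#>    set005 DMD-AGE-  9 40 16 8.519071e-08
```

Real data enter through `readExpressionTsv()` /
`readSampleAnnotation()` / `readProbeMap()` / `readGmt()`, and
clustered results leave through `writeCdtGtr()` for TreeView-style
heatmap viewers.

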