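# gutmarker

Case-control gut microbiome analysis and random-forest disease markers for
ASV-level 16S rRNA data.

## What it does, and for whom

Clinical microbiome studies that compare patients against matched healthy
controls tend to follow one statistical arc: alpha diversity (richness and
evenness), beta diversity with ordination and permutation tests, per-taxon
nonparametric comparisons, LDA effect size (LEfSe) biomarker ranking,
taxon–covariate correlation, and finally a random-forest classifier whose
per-sample score — the probability of disease (POD) index — is evaluated by
ROC/AUC on a held-out set. gutmarker implements that entire arc as a
single R package for analysts who start from an ASV count table, a
taxonomy, sample metadata and (optionally) a phylogenetic tree.

The statistical core, in the field's standard notation:

* **Alpha diversity** — observed richness; bias-corrected Chao1
  `S_obs + F1(F1−1)/(2(F2+1))`; ACE with rare cutoff 10; Shannon
  `H = −Σ pᵢ ln pᵢ`; Simpson dominance `D = Σ nᵢ(nᵢ−1)/(N(N−1))`
  (Mothur conventions).
* **Beta diversity** — Bray-Curtis, binary Jaccard, unweighted and
  (normalised) weighted UniFrac over a rooted tree; classical PCoA.
* **Community tests** — PERMANOVA pseudo-F and Clarke's ANOSIM R, 10,000
  permutations, `(1+b)/(1+m)` p-values, automatic exhaustive enumeration
  for small designs.
* **Per-taxon tests** — Mann-Whitney U (exact enumeration with midranks
  for small groups) and Kruskal-Wallis, on relative abundances; Welch-t
  and Yates chi-square helpers for reconstructing baseline-table
  statistics from printed summaries.
* **LEfSe** — Kruskal-Wallis screen at α = 0.05, bootstrapped
  one-component ridge-regularised LDA, log10 effect score, threshold 2.5.
* **Marker model** — candidate screen (p < 0.05 and > 0.1% abundance),
  five-fold cross-validated random-forest marker selection with
  leakage-free in-fold re-ranking, POD index from tree votes (out-of-bag
  for training samples), AUC with DeLong 95% CI.
* **Synthetic data** — Dirichlet-multinomial generator with planted fold
  changes, covariate links via Gaussian copula, random taxonomy and tree,
  and a ground-truth record for recovery testing.

See `vignettes/gutmarker-methods.Rmd` for the full methods account.

## Worked example

Simulate a cohort with the default study shape (27 cases + 27 controls,
976 ASVs, depths 35,925–120,795, five planted fold-change-4 markers), then
run the community tests and the diagnostic model:

```r
library(gutmarker)

ds <- simulate_dataset(synthetic_config(seed = 1))

head(alpha_diversity(ds$counts), 3)
#>   sample_id observed_features    chao1      ace  shannon    simpson
#> 1    CASE01               259 298.0000 283.1442 4.060121 0.05509457
#> 2    CASE02               256 267.8750 276.0359 3.961706 0.06610620
#> 3    CASE03               278 291.1429 294.4941 4.162199 0.04678068

d <- beta_distance(ds$counts, "jaccard_binary")
permanova(d, ds$metadata$group, seed = 2)
#> PERMANOVA: statistic = 1.165, p = 0.032397 (10000 permutations)
anosim(d, ds$metadata$group, seed = 3)
#> ANOSIM: statistic = 0.044138, p = 0.026097 (10000 permutations)

ev <- train_test_evaluate(ds$counts, ds$metadata$group,
                          disease = "case", seed = 6)
ev$manifest$markers
#> [1] "ASV0306" "ASV0485" "ASV0936" "ASV0166" "ASV0435" "ASV0495"
ds$truth$differential$feature_id
#> [1] "ASV0166" "ASV0306" "ASV0485" "ASV0572" "ASV0936"
ev$test_roc
#> AUC = 1.0000 (95% CI 1.0000-1.0000), group-difference p = 0.0004038
```

Reading the output: the two communities differ modestly but detectably at
the whole-community level (PERMANOVA p ≈ 0.03, ANOSIM R ≈ 0.044 — five
shifted ASVs out of 976 are a small perturbation), the selected marker set
contains four of the five planted ASVs plus two correlated passengers, and
the POD index separates held-out cases from controls perfectly at this
effect size.

The same analysis runs end-to-end from files via `run_pipeline()` with a
YAML or in-code configuration (see `?run_config`), writing per-stage TSVs
and a manifest with MD5 hashes; `pipeline_report()` renders a markdown
summary. A thin command-line front-end is provided in
`inst/scripts/gutmarker-pipeline.R`.

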