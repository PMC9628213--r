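---
title: "Statistical methods in gutmarker"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods in gutmarker}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gutmarker)
```

gutmarker is a case-control analysis pipeline for ASV-level 16S rRNA gut
microbiome data. It covers the standard arc of such a study — alpha and beta
diversity, community-level permutation tests, per-taxon comparisons, LDA
effect size (LEfSe) biomarker discovery, taxon-covariate correlation, and a
random-forest diagnostic model scored by a probability-of-disease (POD)
index — together with a synthetic data generator that emits ground truth, so
every stage can be validated without sequencing data. This vignette explains
the models, the defaults and the numerical choices.

## Data model

The central object is a `count_table`: an integer matrix of ASV counts,
features as rows, samples as columns, with unique identifiers and strictly
positive per-sample totals. Taxonomy is a seven-rank lineage table
(kingdom through species); ranks without an assignment carry a
rank-prefixed sentinel such as `g__unclassified`, so genus-level aggregation
pools unassigned ASVs *within* their parent family (the
`Enterobacteriaceae_unclassified` style familiar from SILVA-annotated
tables) rather than into one global bin. Trees are `ape` `phylo` objects;
unrooted input is midpoint-rooted, because UniFrac needs a root and midpoint
rooting is the neutral choice when no outgroup is available.

## Alpha diversity

Per sample, `alpha_diversity()` reports observed richness, bias-corrected
Chao1, ACE with the conventional rare/abundant cutoff at 10 reads,
Shannon-Wiener entropy in natural log, and Simpson's index. Two conventions
matter and both follow Mothur, the tool classically used for these metrics:

* Chao1 uses the bias-corrected form $S_{obs} + F_1(F_1-1)/(2(F_2+1))$
  rather than the classic $F_1^2/(2F_2)$, so it is defined when doubletons
  are absent.
* Simpson is reported in the small-sample dominance form
  $D = \sum_i n_i(n_i-1)/(N(N-1))$; the complement $1-D$ is provided as a
  separate column for users who expect the "diversity" orientation.

ACE is undefined when every rare feature is a singleton (the sample-coverage
estimate is zero); the package returns `NA` for that sample rather than
guessing.

Rarefaction (`rarefy()`) subsamples each sample without replacement to an
even depth, and `expected_rarefied_richness()` provides the hypergeometric
closed form $E[S] = \sum_i \left(1 - \binom{N-n_i}{d}/\binom{N}{d}\right)$
used to validate it. No rarefaction is applied by default before diversity
computations; an explicit `rarefy_depth` option exists in the pipeline
configuration for users who prefer even-depth analysis. The default keeps
all reads because subsampling discards data and the permutation tests
downstream do not require equal depths.

## Beta diversity and community-level tests

`beta_distance()` implements Bray-Curtis, binary Jaccard, and both UniFrac
variants. UniFrac works on per-branch descendant mass obtained by a single
postorder accumulation over the rooted tree; unweighted UniFrac is the
unshared fraction of branch length spanned by either sample, and weighted
UniFrac is $\sum_e b_e |p_e^A - p_e^B|$, normalised by
$\sum_e b_e (p_e^A + p_e^B)$ unless the raw variant is requested. On a star
tree with unit branches, unweighted UniFrac reduces analytically to binary
Jaccard — the test suite exploits this identity.

Ordination uses classical metric scaling of the double-centred squared
distance matrix; axes with negative eigenvalues (common for non-Euclidean
dissimilarities) are reported in the eigenvalue spectrum but carry no
coordinates, and variance explained is taken over the positive part.

`permanova()` partitions the total sum of squared distances and tests the
pseudo-F by label permutation; `anosim()` tests Clarke's rank-based R
statistic, $R = (\bar r_B - \bar r_W)/(M/2)$ with $M = n(n-1)/2$ pairwise
distances under midranks, whose denominator is the maximum achievable
rank-mean difference so that complete separation gives exactly $R = 1$.
Both use 10,000 permutations by default and the $(1+b)/(1+m)$ estimator, so
a permutation p-value is never zero. When the number of distinct label
assignments is at most 20,000 the tests switch to exhaustive enumeration
automatically, which makes small-n results exact and seed-independent.

## Per-taxon comparisons

`group_compare()` uses the Mann-Whitney U test for two groups and
Kruskal-Wallis for more. The Mann-Whitney implementation enumerates all
label assignments exactly (midranks, valid under ties) when both groups
have at most 8 samples, and otherwise uses the tie-corrected normal
approximation with continuity correction. Comparisons run on relative
abundances by default because composition is the scale on which results are
reported; raw p-values are emitted by default (with an optional
Benjamini-Hochberg column), matching the common practice of screening taxa
at raw p < 0.05 before effect-size ranking.

The baseline-table helpers reconstruct tests from printed summaries:
`welch_t_from_summary()` applies the unequal-variance t-test (the variant
consistent with the printed p-values of the cohort table this package was
validated against; the pooled Student test is one flag away), and
`yates_chi2_2x2()` the continuity-corrected chi-square.

Spearman correlation maps use midrank $\rho$ with the t-approximation
p-value on pairwise-complete observations, and tier pairs as `strong`
(p <= 0.01) or `moderate` (0.01 < p <= 0.05) — the convention used for
solid versus dotted edges in correlation heatmaps.

## LEfSe

`lefse()` is a from-scratch implementation of the LDA effect size
procedure: total-sum scaling to $10^6$ per sample, a Kruskal-Wallis screen
at $\alpha = 0.05$, then 30 bootstrap rounds (two-thirds of each class,
with replacement) of a one-component Fisher discriminant over the surviving
features. A feature's effect size averages its share of the projected
class-mean gap and its raw class-mean difference; the LDA score is the
log10 of the bootstrap mean, floored at 0, and the default reporting
threshold is 2.5. Design choices:

* The subclass (within-class Wilcoxon) stage of the canonical tool is a
  no-op here because the supported designs have classes only.
* The pooled within-class covariance is ridge-regularised with
  $\varepsilon = 10^{-6} \times \mathrm{trace}$, so sparse taxa with
  zero within-class variance (which pass the Kruskal-Wallis screen
  regularly in microbiome data) cannot make the discriminant singular.
* With more than two classes, each class is contrasted one-against-all and
  a feature is scored on the contrast of its enriched class (the class
  with the larger mean normalised abundance).

Bootstrap count and fraction follow the canonical tool's defaults; exact
bit-compatibility with the canonical implementation's random stream is not
a goal.

## The diagnostic marker model

The marker pipeline mirrors the design of random-forest microbiome
classifiers built on a candidate screen:

1. `candidate_filter()` keeps ASVs with raw Mann-Whitney p < 0.05 *and*
   maximum per-sample relative abundance above 0.1% — the "significant and
   non-trivially abundant" rule.
2. `cv_marker_selection()` runs stratified five-fold cross-validation
   (five repeats by default). Inside each training fold, features are
   re-ranked by mean decrease in accuracy from a forest fitted on that fold
   alone, so no held-out information leaks into the ranking; held-out error
   is evaluated along a marker-count grid (every count up to 10, then
   halving steps up to the full candidate set). The optimal count minimises
   mean CV error with ties resolved towards parsimony, and the final marker
   list is the top of the full-training-data ranking at that count.
3. `fit_forest()` fits a 500-tree forest (mtry $=\lfloor\sqrt p\rfloor$) on
   the selected markers with per-tree vote access.
4. `pod_index()` converts votes to the POD: the literal index is the ratio
   of disease votes to control votes; all ranking statistics use the vote
   *fraction*, a strictly monotone transform of the ratio that avoids the
   infinity at unanimous votes. Training samples are scored by their
   out-of-bag trees — resubstitution votes from a forest are nearly pure
   and would make the training ROC meaningless — while test samples are
   scored by the full forest. A `resubstitution` flag overrides this.
5. `roc_auc()` computes AUC by the Mann-Whitney identity with midranks,
   a 95% DeLong confidence interval, and a Mann-Whitney p-value for the
   group difference in POD.

`train_test_evaluate()` chains these with strict train/test separation:
filtering, selection and fitting see training samples only, and the
manifest records the exact sample usage for audit.

## The synthetic data generator

`simulate_dataset()` emulates the shape of a two-arm stool 16S cohort:
27 samples per group, 976 ASVs, per-sample depths uniform on
35,925-120,795 reads. Baseline composition is log-normal (sdlog = 2, a
strongly skewed rank-abundance curve); the case composition multiplies a
small set of planted ASVs by their fold changes and renormalises, so
non-planted features shift only through renormalisation — an effect that is
verified analytically on a three-feature toy in the tests. Counts are
Dirichlet-multinomial with concentration $\theta \times$ composition.

Two generator choices deserve explanation:

* **Overdispersion** defaults to $\theta = 200$. The Dirichlet-multinomial
  is the standard overdispersed null for 16S counts, and $\theta$ is the
  signal-to-noise knob: a pilot power computation showed that at
  $\theta = 200$ a fold-change-4 effect on a moderately abundant ASV is
  reliably detectable by Mann-Whitney at n = 27 + 27, which is the regime a
  study of this design operates in (dozens of candidate ASVs surviving a
  p < 0.05 screen), while much smaller $\theta$ buries even strong effects
  in sampling noise.
* **Planted markers are drawn from features above the 75th percentile of
  baseline abundance.** Real diagnostic ASV markers are detectable taxa —
  the candidate screen itself demands > 0.1% abundance — so planting
  effects on vanishingly rare features would simulate a study that could
  not exist.

Clinical covariates are generated by a Gaussian copula on the normal scores
of the linked ASV's relative abundance, using the classical calibration
$r = 2\sin(\pi\rho_S/6)$ to hit a requested Spearman strength. Taxonomy is
a random nested partition (geometric genus sizes, mean 4) and the tree is a
random bifurcation with exponential branch lengths.

What the generator does *not* emulate: phylogenetic signal in the planted
effects (differential ASVs are not clustered on the tree), taxon-taxon
ecological interactions, zero-inflation beyond what the
Dirichlet-multinomial produces, and batch or sequencing-run structure.
Passing the recovery and calibration tests therefore demonstrates that the
statistical machinery is correct and well-calibrated under a realistic
marginal model, not that any particular biological dataset will yield
markers.

## Calibration and problem sizes

The test suite validates the stack in both directions. Under the null
(identical compositions in both groups) per-feature Mann-Whitney p-values
are uniform — checked by a Kolmogorov-Smirnov test restricted to features
present in at least half the samples, where the null distribution of the
statistic is effectively continuous; PERMANOVA rejects at the nominal 5%
rate over 50 replicate null cohorts at 10,000 permutations; LEfSe passes at
most ~5% of features; and the held-out AUC of the full marker pipeline
stays within [0.2, 0.8] in at least 19 of 20 seeds. Under planted signal,
the candidate filter captures all five fold-change-4 markers in at least
95% of seeds, cross-validated selection recovers at least 4 of 5 in at
least 80% of 25 seeds, and an 18+18/9+9 split at fold change 6 reaches a
held-out AUC of at least 0.9. The replicated simulations use 200-tree
forests with two CV repeats — the selection behaviour is already stable
there, and the defaults (500 trees, five repeats) are used for single
end-to-end runs.

## Numerical and degenerate-input choices

* Permutation p-values use $(1+b)/(1+m)$; exhaustive enumeration replaces
  sampling automatically for small designs.
* Constant features: Kruskal-Wallis is skipped (p = 1, flagged), Spearman
  returns `NA` with a reason, LEfSe excludes the feature.
* All-zero samples are rejected at construction; all-zero features are
  allowed and simply never detected.
* Ties are handled by midranks throughout (Mann-Whitney, ANOSIM, Spearman,
  AUC).
* Every stochastic routine takes an explicit seed and the pipeline
  manifest records MD5 hashes of all outputs; two runs with the same
  configuration and seed are byte-identical.

## Limitations

The LEfSe scores agree with the canonical tool in structure but not
bit-for-bit (different RNG and LDA solver). DeLong intervals are asymptotic
and can be degenerate when the AUC is exactly 1 — they are clamped to
[0, 1]. The subgroup machinery reuses the main-contrast operations verbatim
on metadata-defined sample subsets; subgroup levels with fewer than three
samples are skipped rather than tested. Survival-time modelling and
functional (pathway) prediction are out of scope, although LEfSe accepts
any non-negative feature table, including externally predicted pathway
abundances.
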