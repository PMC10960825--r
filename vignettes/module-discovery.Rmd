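---
title: "Consensus multi-omic module discovery: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus multi-omic module discovery: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Case-control microbiome studies increasingly pair several molecular layers
for the same stool or serum samples: species-level taxonomic profiles
("T"), pathway-level functional profiles ("P"), and fecal or serum
metabolite intensities ("M"/"S"). Feature-by-feature testing of such data
yields long, layer-blind marker lists. `modulomics` instead looks for
*disease-associated multi-omic modules*: small sets of features drawn from
two or more omics that (i) co-vary with each other across samples and (ii)
jointly separate cases from controls. A module is a candidate mechanism —
e.g. a handful of species together with the metabolites they produce —
rather than a ranked list of isolated markers.

## The model

### Sparse generalized CCA with the phenotype as a block

Let $X_1, \dots, X_J$ be the per-omic feature matrices (samples in rows,
columns standardized to mean 0, SD 1), and let $y$ be the centered,
unit-SD encoding of the binary phenotype, treated as one extra block with
a single feature. sGCCA finds one sparse loading vector $a_j$ per block so
that the block variates $t_j = X_j a_j$ maximise

$$\sum_{j < k} c_{jk}\, \mathrm{cov}(t_j, t_k), \qquad \lVert a_j \rVert_2 = 1,
\quad \lVert a_j \rVert_0 = \texttt{keep}_j ,$$

where $C = (c_{jk})$ is the block design matrix. Every omic pair is
weighted `des` (default 1, fully connected) and every omic–label pair is
weighted 1, so the optimisation balances cross-omic covariance against
covariance with the phenotype. The features with non-zero loadings across
the omic blocks of one component form a *putative module*; `ncomp`
components are extracted by regression deflation
($X_j \leftarrow X_j - t_j t_j^\top X_j / t_j^\top t_j$), which makes
within-block variates of successive components orthogonal. The label
block is never deflated, so every component remains phenotype-aware.

Numerically, each component is fitted by block-coordinate ascent: block
$j$'s raw direction $X_j^\top \sum_k c_{jk} t_k$ is soft-thresholded at
its $(\texttt{keep}_j + 1)$-th largest absolute entry, leaving exactly
`keep` non-zero loadings (ties resolved toward the lower feature index for
determinism). Two numerical choices matter and were made after observing
the plain algorithm fail its own invariants:

* **Monotone ascent.** With an exact non-zero count the threshold moves
  between sweeps, and raw updates can *decrease* the criterion (we
  observed drops of order $10^{-3}$, particularly after deflation). Each
  block update is therefore greedy: a candidate loading is accepted only
  if the criterion does not decrease. One unconditional sparse sweep first
  imposes the support constraint on the dense warm start.
* **Multi-start on narrow blocks.** Coordinate ascent on very small
  blocks is prone to local optima: with single-feature supports on
  3-feature blocks, a single deterministic start missed the global
  optimum on roughly one instance in ten. The fit therefore always runs
  a dense warm start (each block's dominant right singular vector,
  relaxed for a few sweeps) and, for blocks of width at most
  `restart_width` (default 12), restarts from every signed basis vector
  of that block, keeping the best criterion. On 200 random keep-1
  instances this reproduces the exhaustive-search support every time; at
  pipeline scale (blocks of width ~100) the restarts are inactive and the
  cost is a single fit.

### Consensus over subsamples

A single sGCCA fit is sensitive to individual samples and to `keep`. The
pipeline therefore refits on `n_runs` (default 100) label-stratified
subsamples, each holding $(\texttt{nfol}-1)/\texttt{nfol}$ of the samples
(default 4/5 = 80%), and counts, for every unordered feature pair, the
fraction of runs in which the pair shared a putative module (a pair
appearing in several components of one run counts once, keeping
frequencies in $[0,1]$). Pairs co-occurring in at least `edge` (default
0.8) of runs become edges of the consensus network; connected components
with $\ge 2$ features are the *consensus modules*. Stratification keeps
class proportions within one sample of the full data in every subsample,
which protects small cohorts from class-empty runs.

### Evaluation against size-matched null modules

Passing the consensus filter proves stability, not disease relevance. Each
consensus module is summarised by the first principal component of its
(scaled and centered) feature submatrix and scored by the rank-based AUC
of that PC against the labels, folded to $\max(A, 1-A)$ because a PC's
sign is arbitrary — without folding, null AUCs would be ill-defined.
Cross-omic coherence is the mean Spearman correlation over all feature
pairs spanning two omics (signed by default; `rho_absolute` switches to
magnitudes). Both statistics are benchmarked against `n_null` (default
100) random modules drawn with the same per-omic feature counts. A module
is *disease-associated* iff it spans $\ge 2$ omics, its AUC exceeds
`auc_threshold` (default 0.7), and both statistics exceed the null mean
(`exceedance = "q95"` substitutes the null 95th percentile for a stricter
rule). The module AUC is deliberately in-sample — it describes the
discovered axis — while the cross-validated forest on module PCs
(`modules_pc_rf()`) provides the honest out-of-sample counterpart, with
PCA loadings refitted inside each training fold.

## Preprocessing

Per omic, in this order:

* **Taxa / pathways**: total-sum scaling to relative abundances; removal
  of constant features, features non-zero in under `min_prevalence`
  (default 15%) of samples, and features with mean relative abundance
  under `min_mean_abundance` (default $5\times10^{-5}$, i.e. 0.005%);
  removal of features on a user-supplied exclusion list (the stand-in for
  curated non-bacterial pathway annotations); collinearity collapse.
* **Metabolites**: prevalence/constancy filtering on the *raw*
  intensities (after a log transform zeros are no longer zeros, so
  prevalence must be assessed first); natural-log transform with a
  pseudocount of half the smallest positive value per feature (features
  without zeros get none); collinearity collapse.

Collinearity collapse clusters features whose pairwise absolute Spearman
correlations all exceed `collinearity_threshold` (default 0.99, complete
linkage) and keeps one seeded-random representative per cluster. Because
collapsing two clusters can leave their representatives above the
threshold, the step iterates to a fixed point; the output provably
contains no pair above the threshold. Spearman was chosen over Pearson as
rank-robust for abundance data; the threshold is configurable.

Inside each subsampled fit, blocks are re-standardized using the
subsample's own means and (n−1) SDs, so no information about held-out
samples leaks into a run.

## The random-forest baseline

`early_integration_cv()` concatenates all omics and estimates disease
predictability by repeated stratified cross-validation (default 5 folds
× 10 repeats = 50 fold-models, 500-tree `ranger` forests, default
hyperparameters). Within each training fold an all-relevant shadow-feature
procedure screens features: every candidate gets a permuted "shadow"
copy, a forest with permutation importance is fitted, and a candidate
scores a hit when it beats the best shadow; candidates whose hit counts
fall binomially significantly below chance are dropped early, and the
selected set is every feature with a final hit fraction $\ge 1/2$. The
per-feature importance is the permutation importance averaged over all
fold-models, counting models that did not select the feature as zero —
averaging only over selecting folds would condition on having looked
informative and bias the importance upward. Significance comes from a
label-permutation null (`feature_importance()`): the forest is refitted
on permuted labels `n_label_perms` times (default 100) and
$p = (1 + \#\{\text{null} \ge \text{obs}\})/(B+1)$, BH-corrected within
the tested feature set. *Contributors* are features selected in at least
half the fold-models with $q < 0.1$.

## Cross-study comparison

`module_overlap_test()` restricts two modules to the feature universe
shared by both datasets and applies a two-sided Fisher's exact test to the
2×2 in/out table (enrichment-only available via `alternative =
"greater"`); pairs overlapping in fewer than two features are recorded but
untested, and BH correction at $q < 0.1$ runs over the tested pairs. The
genus co-occurrence test asks whether species in modules co-occur with
congeners more than chance: the statistic is the percentage of species
occurrences sharing a genus with another species in the same module,
pooled over modules and datasets; the null redraws each module's species
uniformly from its dataset's species universe, preserving module sizes,
with $p = (1 + \#\{\text{null} \ge \text{obs}\})/(n_{\text{perm}}+1)$.
Genus is parsed as the first whitespace token of the species name unless
an explicit genus map is supplied.

## The synthetic benchmark

`simulate_multiomics()` generates datasets with known ground truth so
every stage is testable without external data. Each planted module $m$
has a latent factor $z_m = 2\alpha_m(\text{label}-\tfrac12) +
\mathcal N(0,1)$; each planted feature tracks it on the log scale as
$\beta z_m + \sigma\,\mathcal N(0,1)$. Taxa and pathways are lognormal
counts closed to relative abundances (compositional, no zero-inflation
unless a `dropout` rate is set); metabolites are lognormal raw
intensities whose log the preprocessing recovers. The defaults — 200
samples, 100 T + 100 P + 60 M features, one planted (5,5,5) module with
$\alpha = 1.5$, $\beta = 1$, $\sigma = 0.7$ — define the benchmark used
throughout the tests and the acceptance script: a clearly detectable but
noisy cross-omic signal at a realistic cohort size.

Two caveats calibrate what passing tests show about real data. First,
closure couples features: when a planted taxon shifts strongly with the
label, *background* taxa inherit an inverse association through the
shared denominator, exactly as in real compositional data — so
"background" taxa are not a clean negative control, and the generator's
metabolite backgrounds serve that role instead. Second, the generator
does not emulate sequencing depth, batch structure, covariates, or
realistic effect-size spectra; recovery of its planted modules
demonstrates correctness of the machinery, not expected performance on
any particular cohort.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `keep` | 10 per omic | non-zero loadings per omic and component; the main sparsity dial. The default is a deliberately generous heuristic — consensus filtering, not `keep`, controls final module size |
| `des` | 1 | omic–omic design weight; 0 routes all coupling through the label |
| `n_runs`, `nfol` | 100, 5 | subsampled refits and subsample fraction (4/5) |
| `ncomp` | 5 | putative modules recorded per run |
| `edge` | 0.8 | co-occurrence frequency required for a consensus edge |
| `auc_threshold` | 0.7 | module PC1 AUC gate |
| `n_null` | 100 | size-matched random modules per observed module |
| `seed` | 1 | master seed; child seeds are derived per stage so extra null draws never perturb the subsampling |

## Known limitations

* Binary phenotypes only; one label block.
* Linear, first-PC summaries: a module whose disease association is
  non-monotone will be missed.
* The in-sample module AUC is optimistic by construction; always read it
  against the null-module benchmark and the cross-validated forest.
* Consensus components can chain two tight sub-modules through a single
  bridging feature; the per-pair edge list in the output makes such
  bridges visible.
* Cross-study comparisons require feature identifiers harmonised upstream.
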