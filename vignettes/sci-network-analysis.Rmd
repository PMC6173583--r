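---
title: "Methods: coexpression network meta-analysis of the spinal cord injury transcriptome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coexpression network meta-analysis of the spinal cord injury transcriptome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(scinet)
```

## The scientific problem

Spinal cord injury (SCI) triggers a coordinated, multi-pathway molecular
response that decades of small-scale experiments have probed one gene at a
time. `scinet` implements an integrative strategy: genes implicated in SCI
by small-scale experiments (a *literature-curated*, LC, set) are validated
as a coherent biological module against protein-interaction data, then
embedded in a genome-wide coexpression network built from healthy spinal
cord expression. Module-level meta-analysis across injury studies yields a
consensus network signature of SCI; severity scoring and hub-gene analysis
nominate quantitative biomarkers of injury severity.

Every stage is exercised end-to-end on synthetic data with planted
structure, so the pipeline's statistical behaviour is testable without any
external download.

## Expression preprocessing

Abundance matrices are filtered to genes exceeding 0.1 (strictly) in at
least 10 samples, quantile-transformed per sample to the average empirical
distribution (ties receive the mean of their target quantiles), and each
gene is mapped to standard-normal quantiles of its mid-ranks,
`qnorm((rank - 0.5) / n)`. The half-offset is symmetric and avoids infinite
quantiles; mid-ranks handle ties. A subtlety worth knowing: after quantile
normalisation a gene can occupy the same rank in two samples, and the tied
mid-rank quantile then moves the row mean slightly off zero — rows without
rank ties sit exactly on the quantile grid with mean zero.

## Ortholog mapping

Rodent and rabbit accessions are mapped to human genes by majority vote
across ortholog databases: counting only databases that contain an entry
for the source id, a human gene is accepted iff proposed by at least half
of them (ceiling). If two distinct human genes both meet the bar, the id is
ambiguous and dropped rather than arbitrated — a conservative choice that
trades recall for precision, logged at parse time.

## Signed coexpression networks

Pairwise similarity is the biweight midcorrelation: samples are weighted by
`(1 - u^2)^2` with `u = (x - med) / (9 MAD)`, so points far from the median
contribute nothing. At most 5% of samples per side of the median may
receive zero weight; where more would, the denominator is inflated on that
side. Genes with zero MAD (more than half their values identical) fall back
to Pearson standardisation, since the biweight weights degenerate there.

The signed adjacency is `a = ((1 + cor)/2)^beta`, mapping correlation -1 to
0 so anti-correlated genes are maximally distant. The power `beta` is the
smallest candidate whose connectivity distribution satisfies the
scale-free fit criterion `R^2 > 0.8`, computed by regressing `log10 p(k)`
on `log10 k` over 10 equal-width connectivity bins (empty bins skipped,
fit sign-adjusted so an increasing trend can never qualify). On factor-model
synthetic data the criterion is typically not met — block structure is not
scale free — and the maximum-fit power is used with a flag; on real tissue
data powers around 5 are typical.

Topological overlap combines direct adjacency with shared neighbourhoods,
`TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)`, and
modules are branches of the average-linkage dendrogram of `1 - TOM`.

### Tree cutting

We use a deterministic adaptive variant: the dendrogram is cut just below
its top joins (at 0.99 of the maximum merge height), and a branch is
accepted as a module only if it is *cohesive* — member genes must show mean
intra-branch TOM at least `cohesion_z` (default 0.5) global standard
deviations above the overall mean TOM; non-cohesive leaves are pruned
iteratively, and at least `min_size` (default 20) genes must remain. On
i.i.d. noise nothing passes the cohesion screen and all genes stay
unassigned; planted correlation blocks are recovered exactly. The variant
is fully specified by the dendrogram, `min_size`, and `cohesion_z`, which
makes tests deterministic; a PAM-like reassignment stage is deliberately
omitted.

Modules whose eigengenes are closer than a dissimilarity of 0.2
(correlation above 0.8) are merged iteratively, eigengenes recomputed after
each merge.

### Eigengenes, kME and hubs

A module eigengene is the first right singular vector of the standardized
member submatrix (unit norm), with sign fixed so its mean correlation with
member genes is non-negative (ties resolve positive). kME is the
correlation of each gene with each eigengene; hubs are the top decile of a
module by kME, ties broken by gene id.

## Module preservation (Zsummary)

Preservation of a reference module in an independent dataset is the
permutation Zsummary: reference labels are transplanted into the test data
and seven statistics are computed — four *density* statistics (mean
intra-module correlation, mean signed adjacency, proportion of variance
explained by the test eigengene, mean kME) and three *connectivity*
statistics (correlation of intramodular connectivity, of kME, and of the
vectorized intra-module correlation matrix, reference vs test). The null
reassigns module labels uniformly at random over the shared universe,
preserving sizes; each statistic's Z is `(obs - mean_perm)/sd_perm`
(statistics with zero permutation spread are omitted from their median),
`Zdensity` and `Zconnectivity` are class medians, and
`Zsummary = (Zdensity + Zconnectivity)/2`, with the conventional bands
>10 strong, 5–10 moderate, <2 absent. Permutations are drawn in a
canonical (sorted) gene order, so results are exactly invariant to input
row/column ordering at a fixed seed. For proteomic data every correlation
switches to Spearman.

A property of the connectivity class worth knowing: when modules occupy a
large fraction of the universe, permuted "modules" mix genes from several
true modules and their reference/test connectivity vectors correlate
strongly (a bimodality artifact), depressing Zconnectivity. The statistic
behaves as intended when modules are a small fraction of the universe, as
in genome-scale data; our tests respect those proportions.

## Interactome validation

All network-null tests share the add-one empirical estimator
`p = (1 + #{null >= obs}) / (1 + N)`, which is never zero and at 1000 nulls
bottoms out at ~1e-3. Null networks preserve the degree sequence by double
edge swaps. One implementation note: the igraph rewiring engine counts
*attempted* swaps, and on heavy-tailed simple graphs a large fraction of
proposals is rejected (they would create loops or duplicate edges). We
therefore attempt three proposals per requested swap; with the default of
`10 |E|` swaps this gives null ensembles statistically indistinguishable
from the stationary configuration-model ensemble, which our calibration
tests verify directly (empirical p uniform under the null).

Observed statistics are the number of interactions among set genes, the
size of their largest connected component, the number of distinct set
pairs sharing a protein complex (nulls: uniform random sets from the
complex universe), and the mean number of shared annotation terms per gene
pair, restricted to terms annotated to at most 100 / 1000 / all genes
(breadth cutoffs; the mean over pairs makes different set sizes comparable
under the null).

DIAMOnD ranks candidate disease genes by iteratively adding the node with
the most significant hypergeometric connectivity to the current seed set
(`k_s` seed neighbours out of degree `k`, drawn from all `N` nodes with the
current seed count as successes); ties prefer higher `k_s`, then
lexicographic id; the added node joins the seeds. Recovery analysis
withholds 20% of a gene set, seeds with the remainder, and compares
recovery ranks of withheld genes against random seed/target controls with
a two-sample one-sided Kolmogorov–Smirnov test; unrecovered targets are
assigned rank `n_iter + 1`.

## Differential-expression meta-analysis

Per study, genes are ranked by the pooled-variance two-sample t statistic
(injured vs sham); severity enters as a continuous covariate through the
Spearman correlation with a t-approximation p. Empirical-Bayes moderation
is deliberately not applied: the downstream set test consumes ranks, which
moderation perturbs only marginally.

The module-level test is a mean-rank (Wilcoxon rank-sum) comparison of the
statistics of module genes against all other genes, one-sided for up- and
for downregulation. Exact enumeration is used when both groups have at
most 10 members and no ties; otherwise the normal approximation with tie
and continuity corrections. Bonferroni correction spans modules x 2
directions within each study; the per-study call threshold is adjusted
p < 0.05. Consensus labels require the same significant direction in every
study; "majority" allows one exception. Temporal profiles rerun the
analysis within each timepoint stratum and flag modules whose call
direction flips between the earliest and the latest timepoint.

An important caveat the null-calibration tests make explicit: gene-set
rank tests assume exchangeable genes. When module genes share a latent
factor, their statistics are correlated and the test is anti-conservative
even without any true effect. Our calibration tests therefore zero the
coexpression signal as well as the effects; on real data, module-level p
values should be read as descriptive enrichment scores, with consensus
across independent studies carrying the inferential weight.

## Severity scores and reversal

The per-gene severity score is `s = rho * (-log10 p)` from the Spearman
correlation with injury severity; module enrichment for positively and
negatively scored genes uses the same mean-rank machinery (Bonferroni over
modules x 2), and each module's eigengene is correlated with severity
directly. The reversal test asks whether consensus modules move opposite
to their injury direction under a treatment contrast: a one-sided
mean-rank test with the alternative fixed by the reversal hypothesis, plus
a one-tailed Wilcoxon rank-sum test on the eigengene sample scores (exact
for the small group sizes involved).

## Cell types and biomarkers

The specificity index is a rank-mean statistic: for gene g and cell type c,
the average over other cell types of the rank of the pseudocounted log2
fold change (rank 1 = most enriched), with a permutation p from shuffling
gene labels within each pairwise comparison. This is a declared rank-mean
approximation of the published specificity-index approach, not a numerical
replication of it. Module x cell-type enrichment is Fisher's exact test on
specific genes at thresholds 0.05/0.01/0.001/0.0001, Bonferroni-corrected
over modules x cell types per threshold.

Biomarker evaluation is two-class linear discriminant analysis with pooled
covariance and equal priors (group sizes are balanced by design), assessed
by leave-one-out cross-validation; sham samples are excluded from
moderate-vs-severe classification. A singular pooled covariance is
ridge-regularised by `1e-6 * trace(S)` with a warning. The implementation
is cross-checked against MASS::lda in the test suite but kept explicit so
degenerate single-feature inputs behave predictably.

## The synthetic-data generator

The generator defines the study conditions everything else is tested
under. Expression follows a single-latent-factor model per module:
`x_gs = lambda_g e_ms + eps_gs` with `e` standard normal per sample and
`eps ~ N(0, noise_sd^2)`. Defaults:

* 400 genes, five modules of 60/50/40/30/20, 71 reference samples (a
  typical post-mortem cohort size), `module_signal = 0.9`,
  `noise_sd = 0.2` — a high-SNR regime in which module recovery should be
  essentially exact (the recovery tests assert ARI >= 0.9).
* Per-gene loadings are drawn uniformly from 0.4–1.2 x `module_signal`,
  giving each module a hub-to-periphery continuum: this is what real
  modules look like, and it is what makes kME-based hub selection and the
  connectivity class of the Zsummary informative.
* Five injured-vs-sham test studies of 32 samples, timepoints 1/3/7/28
  days; planted module effects +2/-2/+2/+10/+2 eigengene units, the fifth
  module's effect reversing sign from the earliest to the latest timepoint
  (an acute-down/chronic-up module). All injured samples sit at the
  maximal severity, so these studies are binary contrasts.
* A dedicated graded-severity study (sham/100/200 kdyn, 5 animals per
  level, day 7) in which only the severity-coupled module responds,
  linearly in severity. The strong default coupling (+10) places the top
  hub in the regime where it stratifies moderate vs severe injuries
  perfectly, mirroring a strong single-gene severity biomarker; the
  hubness-vs-accuracy analyses use a milder coupling with gene-level noise
  comparable to the factor scale (`noise_sd = 1`): because a gene's loading
  scales its severity signal and its factor noise alike, a hubness gradient
  in single-gene accuracy only exists when measurement noise is
  appreciable, and per-gene accuracy is averaged over replicate severity
  studies to stabilise the correlation's sign.
* Module factors in test and severity studies are residualized against the
  study's severity design before shifts are added. At these sample sizes
  the chance correlation between a latent factor and the design
  (~1/sqrt(n)) would otherwise shift whole modules coherently, and set
  tests would amplify it into spurious calls; orthogonalization makes the
  planted effects the only design-aligned signal, which is what makes the
  recovery and uniqueness tests identifiable. Real data do not enjoy this
  property — another reason consensus across studies, not single-study p,
  is the unit of inference.
* The interactome has 3000 nodes (the 400 expression genes plus
  genome-background genes), power-law degrees with exponent 2.5 and mean
  degree 6, mixed by a degree-preserving edge-swap burn-in so the observed
  graph is exchangeable with its rewired nulls, then edges are planted
  among the curated true positives to density 0.2. The genome-scale node
  set matters: a curated set must be a small, subcritical fraction of the
  network for the largest-connected-component statistic to discriminate.
* The curated set has 80 genes: 70% true positives drawn from two target
  modules, 30% uniform false positives; records carry synthetic species,
  techniques, models, timepoints and study ids, with three ortholog
  databases (each missing ~10% of entries) so majority voting is
  exercised on ingest.
* Annotations span three categories and three breadth classes (small 5–20,
  medium 30–80, large 120–200 genes, capped by the universe); 80% of
  small/medium terms are module-concordant. Cell-type profiles are
  log-normal with the marker module 8x elevated in its designated type.
* Every generator draws from its own stream derived from `rng_seed`
  (fixed offsets), so adding one output never perturbs another, and a
  configuration plus seed determines all outputs bit-for-bit.

What the generator does **not** emulate: negative-binomial count noise,
probe-level microarray artifacts, batch effects, correlated measurement
error, or annotation incompleteness. Passing tests therefore demonstrate
the statistical machinery is correct and calibrated under its own
assumptions, not that effect sizes on real data will match.

## Problem sizes and numerical choices

The test-suite and acceptance analyses run at deliberately compact sizes:
interactome calibration uses 120-node graphs with 99 rewired nulls and 200
replicates; preservation uses 100 permutations (the conventional count);
DIAMOnD recovery uses 200 iterations and 30 bootstraps in the acceptance
summary. Degenerate inputs are handled explicitly: constant genes get
kME 0 and inverse-normal rows of zeros (with warnings), zero-MAD genes
fall back to Pearson, zero-spread permutation statistics are omitted from
the Zsummary medians, an all-zero matrix fails filtering with an error
naming the condition. Matrix symmetry is enforced to 1e-10 and
adjacency/TOM entries clamped to [0, 1] against floating-point drift.

## A worked run

```{r pipeline}
cfg <- sim_config(rng_seed = 7)
sim <- simulate_sci(cfg)

part <- build_coexpression_network(sim$reference)
glance(part)
adjusted_rand_index(part$labels, sim$truth$module_labels)

pres <- zsummary(sim$truth$module_labels, sim$reference, sim$studies[[1]],
                 n_perm = 100, rng_seed = 1, beta = 5)
autoplot(pres)

de <- module_de(sim$studies, part)
consensus_calls(de)

sev <- severity_scores(sim$severity_study, sim$truth$module_labels)
tidy(sev)
```

## Known limitations

* The tree-cut variant is not the hybrid dynamic cut with PAM stage; on
  real tissue data module counts and boundaries will differ in detail.
* The specificity index is a rank-mean approximation, not the published
  package's exact statistic.
* Mean-rank module tests are anti-conservative under inter-gene
  correlation (see above); Bonferroni families are pinned within study.
* Empirical network p-values are bounded below by `1/(N+1)`; claims below
  1e-3 require more than 1000 nulls.
* Block-wise decomposition is not implemented; matrices are dense, so the
  practical ceiling is roughly 20–30k genes on a workstation.
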