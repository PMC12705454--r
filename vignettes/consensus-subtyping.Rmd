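---
title: "Consensus transcriptomic subtyping of sepsis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus transcriptomic subtyping of sepsis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Whole-blood transcriptomics has produced several competing molecular
subtype systems for sepsis — a 2-class sepsis response signature (SRS), a
4-class system (Mars1–4), and a 3-class system (inflammopathic, adaptive,
coagulopathic). Each system partitions patients differently, which has
blocked clinical translation. `ctsepsis` implements a framework that
reconciles such partitions into *consensus transcriptomic subtypes* (CTS):
it measures the agreement structure between all subtype pairs across
systems, clusters the resulting network, derives a compact gene classifier
from the patients on which all systems agree, and stress-tests the result
with de novo clustering, single-cell projection and subtype-stratified
clinical analysis.

## The model, step by step

**Harmonization.** Input expression is log-scale (log2 intensity or
log-CPM), transcripts × samples. Transcripts are collapsed to unique genes
by the per-sample arithmetic mean (`collapse_transcripts()`), then
platform/batch effects are removed by parametric empirical-Bayes
adjustment (`combat_adjust()`): per-gene standardization against the
batch-size-weighted grand mean and pooled variance, per-batch location
(γ) and scale (δ²) estimates shrunk toward method-of-moments
normal/inverse-gamma priors, and back-transformation. The design contains
batch only — no biological covariates — because the subtype labels that
enter downstream analysis must not be regressed out. We implement the
estimator inside the package because downstream reporting needs the
shrunken per-batch parameters themselves; the test suite checks exact
agreement (≈1e−6) of the adjusted matrix with the `sva` reference
implementation. One subtlety worth stating: empirical-Bayes shrinkage does
*not* exactly preserve the per-gene pooled mean — the residual is of the
order of the shrinkage — so we assert mean preservation only up to that
residual, not to machine precision. Genes with zero pooled variance
cannot be standardized and are dropped with a message.

**The subtype network.** For every pair of subtypes from *different*
systems we compute the Jaccard index of their member sets, a permutation
p-value (one system's labels permuted over samples; add-one estimator
`(1 + #{J* ≥ J})/(n_boot + 1)` so p is never 0), and a one-sided
hypergeometric overlap p-value with the shared sample set as the
universe. Hypergeometric p-values are Benjamini–Hochberg adjusted over the
full cross-system family (26 pairs for systems of 2/4/3 classes).
Within-system pairs are disjoint by construction and carry no information,
so they are not edges. Edges are kept regardless of significance — the
q-value is an attribute used by the consensus-mapping step.

**Markov clustering.** The Jaccard-weighted network is partitioned with
MCL: column-normalize the weight matrix (self-loops added with the node's
maximum incident weight, which keeps the result invariant to uniform
rescaling of weights), then alternate expansion (matrix square) and
inflation (element-wise power with renormalization), pruning entries below
1e−5, until the flow matrix stabilizes (max absolute change < 1e−6;
iteration cap 5000 — low inflations converge slowly but the matrices are
tiny). Clusters are read from the attractor structure; a node attracted by
several attractor systems joins the one receiving its largest flow mass,
ties to the lowest cluster index. Inflation controls granularity: we sweep
factors 1–7 (10 repeats each to confirm stability), score each partition
by the mean node silhouette on one-minus-Jaccard distance, and keep the
inflation with the best silhouette, ties toward the smaller factor. On the
synthetic design the selected inflation is 2 and yields three clusters.

**From clusters to CTSs and core samples.** Every multi-node cluster
becomes a CTS. A strict partition cannot express that a 2-class system's
subtype serves two consensus groups, so member sets are augmented: when a
cluster lacks a member from some system, the subtype(s) of that system
with BH-adjusted hypergeometric q < α against a cluster member are added.
We deliberately restrict augmentation to these *system gaps*; attaching
every significantly overlapping subtype would let a coarse subtype drag
its whole neighborhood into one member set and make member sets
near-universal. Singleton nodes (the Mars4 analogue) stay unassigned by
default. A sample is *core* for a CTS when, for every system, its label
lies in that CTS's member set; samples matching several CTSs are counted
but treated as non-core so core sets are disjoint. Under independent
labeler errors the core fraction approximates the product of the
per-system concordances, which the tests verify against the realized (not
nominal) concordances of each simulated cohort.

**The gene classifier.** Using core samples only, genes are ranked by
one-vs-all Kruskal–Wallis tests per CTS (vectorized rank-sum computation
with tie correction, verified against `kruskal.test`), ordered by best
one-vs-all p (ties: largest H, then gene id) and truncated at 5000.
Panel size is chosen by stratified tenfold cross-validation over the grid
{2, 4, …, 30, 40, 50}; the ranking is recomputed inside each training
fold so selection never sees the held-out fold. For each size a
500-tree random forest is trained and misclassification rate, multiclass
Brier score and average correct-class probability are recorded; the
selected size is the smallest with CV error below 5%. The final forest is
fit on the core samples, reports its out-of-bag error, and predicts
posterior probabilities for the whole cohort (argmax labels, ties to the
lowest class index; the fraction of samples with posterior > 0.8 is the
confidence summary). Training on core samples and predicting everyone
reflects the framework's logic: the classifier generalizes the consensus,
it does not re-derive it.

**De novo consensus clustering.** As an independent check on the number
of subtypes, expression is re-clustered with resampling consensus
clustering: 90% of samples and 90% of genes per iteration, 1000
iterations (100 in tests), average-linkage hierarchical clustering on
one-minus-Pearson distance, k = 2–10. The consensus matrix at each k is
the co-clustering frequency among co-sampled pairs. k is selected by the
cophenetic correlation between the full-data distance and the dendrogram
of the consensus matrix; the CDF area, delta-area and consensus
silhouette are reported alongside. Correlating against the *original*
distances matters: the consensus matrix at any crisp k is nearly
ultrametric with respect to itself, so self-referential cophenetic
correlation cannot discriminate k. And because extra clusters beyond the
true number are micro-splits that barely move the consensus dendrogram,
the statistic plateaus above the true k; the selected k is therefore the
smallest within a small tolerance (`k_tol`, default 0.5%) of the maximum
— the parsimonious end of the plateau, in the spirit of the one-SE rule. Item resampling is without
replacement, matching the convention of the standard tool for this
procedure. Agreement between de novo clusters and CTS assignments is
summarized with row-normalized concordance tables.

**Single-cell projection.** CTS gene sets are scored per cell with a
rank-based recovery-curve AUC: genes are ranked within each cell by
decreasing expression — ties, including the zero-inflated tail, broken
uniformly at random under a per-cell seed derived from the cell id, so
scores are reproducible and independent of cell order — and the set's
step recovery curve is integrated over the top 5% of the genome and
normalized by its maximum. The 5% window is the standard default for this
statistic; scores are therefore in [0, 1] and invariant to monotone
transformations of expression within a cell.

**Clinical analysis.** Treatment effects are estimated on a matched
cohort: propensity scores from a maximum-likelihood logistic model,
greedy 1:1 nearest-neighbor matching without replacement on the logit
propensity (processing treated patients in descending propensity), with a
caliper of 1.2 standard deviations of the logit propensity. The 1.2
figure follows the published analysis; it is unit-free there, and the
sd-of-logit convention is the standard interpretation for this kind of
matching. Balance is assessed with standardized mean differences.
Outcome models are binomial logistic regressions of 28-day mortality on
treatment × CTS with Wald intervals and AIC; survival is summarized with
Kaplan–Meier curves and log-rank tests (`survival`). Supporting tests:
Pearson chi-squared omnibus with Bonferroni-corrected column-pair post
hocs, Kruskal–Wallis with Dunn's z post hocs (tie-corrected pooled-rank
formula), classic Levene (ANOVA on absolute deviations from group means;
Brown–Forsythe optional), midrank ROC AUC, and category-free net
reclassification improvement with bootstrap percentile intervals
(category-free because no risk categories are published). Table
percentages are rounded half-up to one decimal, the convention of printed
clinical tables; per-variable denominators are supported because several
published rows use variable-specific denominators.

## The synthetic cohort

`generate_cohort()` draws the study conditions the analysis assumes, with
known ground truth:

* three subtypes with prevalences 0.44/0.19/0.37 (following the
  497/213/412 split of the motivating cohort), 2000 genes by default
  (a deliberate scale-down of the ~7260-gene co-normalized space; tests
  and the acceptance script state their sizes), 30 signature genes per
  subtype shifted by +2 log2 units, residual noise sd 1;
* optional per-batch additive/multiplicative distortions
  (`x' = δx + γ`), the generative inverse of the harmonization step;
* three labeler systems of 2/4/3 classes drawn independently per system
  from row-stochastic confusion matrices with 0.9 concordance by
  default. Mars4 is modeled as a low-prevalence error sink (one fifth of
  the Mars error mass) because its real counterpart is rare and never
  forms a consensus cluster;
* severity covariates correlated with subtype (SOFA, APACHE-type score,
  septic shock, infection site), treatment assigned by a logistic model
  on severity (intercept −3.2, giving ≈28% treated — enough controls for
  1:1 matching to balance), and exponential survival censored at day 28
  with per-subtype baseline hazards (≈16/29/16% untreated 28-day
  mortality) and per-subtype treatment log-hazard ratios (+1.2, +1.2,
  −0.5: harmful in subtypes 1–2, protective in subtype 3).

What the generator does *not* emulate: gene–gene correlation beyond the
planted subtype shifts, platform-specific probe behavior, library-size
artifacts, informative censoring, or label errors correlated across
systems. Passing tests therefore demonstrate that the machinery recovers
the structure it assumes, not that real cohorts satisfy those
assumptions.

## Numerical choices and edge cases

* Hypergeometric tails use the exact distribution function; permutation
  p-values use the add-one estimator; BH is the step-up construction.
* Constant genes get H = 0 (ranked last); zero-variance genes are
  dropped before batch adjustment; zero-variance samples are an error
  for correlation distance.
* Argmax ties in prediction go to the lowest class index; MCL attractor
  ties to the lowest cluster index; inflation ties to the smaller factor.
* Singleton silhouettes are 0 by convention, including the all-singleton
  partition.
* All randomness (cohort draws, permutations, fold assignment, forests,
  tie-breaking, bootstrap) flows from explicit integer seeds.

## Known limitations

The MCL granularity sweep assumes the node silhouette is informative,
which requires at least two clusters at some inflation; a fully connected
homogeneous network is an error ("no structure"). Greedy matching is not
optimal matching; with scarce controls its balance degrades before an
optimal matcher's would. The de novo k-selection rule (cophenetic
correlation) is a heuristic: on weakly separated data it can drift to
neighboring k, which is why the delta-area and silhouette columns are
reported alongside. Reproducing the published gene identities or
real-data percentages requires the original cohorts, which this package
does not ship.

## Problem sizes used in tests

Unit tests run on cohorts of 200–2000 samples and 30–300 genes; the
acceptance checks use the default cohort (1000 samples × 2000 genes), 100
consensus-clustering repetitions over ten seeds, and 250–1000 replicates
for calibration — sizes chosen so the full suite exercises every claim at
desk scale.
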