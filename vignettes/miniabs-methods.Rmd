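---
title: "miniabs: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{miniabs: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistical machinery
behind its absolute single-sample breast cancer subtyper: the model, its
assumptions, the parameters that matter, the numerical and design choices
made where the design was genuinely open, and what the synthetic validation
does and does not demonstrate.

## The model

The classifier assigns one of the five intrinsic subtypes (Basal-like,
Her2E, LumA, LumB, Normal-like) to a single expression profile. Its
features are pairwise gene expression ratios (PGERs): for raw linear-scale
values $e_i, e_j$ of two panel genes in the *same* sample,

$$r_{ij} = \log_2\frac{e_i + 1}{e_j + 1}, \qquad 1 \le i < j \le n,$$

followed by a slack-margin soft-threshold with radius $\alpha \ge 0$ that
zeroes ratios indistinguishable from experimental noise and shrinks the
rest toward zero by $\alpha$:
$r'_{ij} = \operatorname{sign}(r_{ij})\max(0, |r_{ij}| - \alpha)$.

Because both values come from one sample, no cohort normalisation or gene
centering enters the feature; a sample's call is therefore invariant to
cohort composition *exactly and by construction* (this is asserted as a
test, not estimated). The +1 pseudocount keeps the ratio defined at zero
expression and is applied identically to RNA-seq and array intensities;
its side effect is that the feature is only *approximately* invariant to
rescaling a sample by a common factor (exact invariance would need a
0-pseudocount, which is undefined at zero expression). The test suite
checks the rescaling robustness as a stochastic property (fewer than 10%
of strong-signal calls change under factors in [0.5, 2]), not as an exact
claim.

Key assumptions: expression is non-negative and linear-scale
(RPKM/FPKM-like); relative magnitudes *within* a sample carry subtype
information; the five-class label scheme is meaningful for the cohort.

## Construction pipeline

**ssDEG screen.** For each subtype, every gene in a universe (default: the
50 PAM50 genes — a functionally curated pool that shrinks the gene-subset
search space by many orders of magnitude) is tested one-vs-rest with the
Wilcoxon rank-sum test; BH correction is applied within each subtype's
family of tests. The per-subtype family (rather than one pooled family
over all five) matches the structure of per-subtype FDR reporting, where a
weak class can have uniformly high FDRs while other classes have tiny
ones.

*Subtype specificity* is decided in two stages. A gene significant
($q <$ 0.005 by default) somewhere is provisionally assigned to its
smallest-$q$ subtype; the assignment stands only if no *other* subtype's
one-vs-rest test remains significant after the assigned subtype's samples
are removed from the cohort. The naive reading — "significant in exactly
one subtype's test" — is not usable at realistic sample sizes: a gene
cleanly shifted in a single subtype contaminates the "rest" group of every
other subtype's test and gets flagged there too (with the opposite
direction) once per-class $n$ reaches a few dozen, so the naive rule ends
up excluding precisely the most specific genes. The residual check keeps
the intended semantics: a truly one-subtype gene loses all secondary
signal once its subtype is removed, while a gene genuinely shifted in two
subtypes keeps its second signal and is excluded.

Genes significant nowhere are still ranked (by ascending $q$) and flagged
`passed_threshold = FALSE`: small, weakly separated classes — Normal-like
being the canonical example, with reference FDRs around 0.24 — must still
be able to contribute ranked genes to gene-set assembly. Determinism
everywhere: ties in $q$ break by raw $p$, then gene symbol; exactly equal
medians report direction `down` (arbitrary, documented, stable).

The rank-sum p-value is exact for combined $n \le 25$ without ties, and
uses the normal approximation with tie and continuity correction
otherwise; the exact path is validated in the tests against full
enumeration of rank assignments.

**Gene sets.** Level $k$ = four seed genes (ESR1, PGR, ERBB2, MKI67 — the
clinical ER/PR/HER2/Ki-67 axis) plus the top-$k$ ssDEGs of each subtype,
deduplicated, appended rank-major so level-$k$ order prefixes
level-$(k{+}1)$ order. From the shipped reference table, level 1 has 8
genes and level 2 has 13. Pair columns are oriented by gene-set order
(`"Gi/Gj"`, $i<j$); the mirrored ratio is linearly dependent and never
emitted, giving the $n(n-1)/2$ feature dimension.

**Training.** Repeated stratified $k$-fold cross-validation (default 5
folds; 10 repeats as the desk-scale default, 100 for a full-scale run)
over an automatic hyperparameter grid, for four learners: random forest,
radial-kernel SVM, CART and naive Bayes. The grids hold `tune_grid_size`
values per tunable parameter, centred on the learner's customary default:
`mtry` around $\sqrt{p}$ for the forest, cost and kernel width around
$(1, 1/p)$ for the SVM, complexity around $10^{-2}$ for CART. Gaussian
naive Bayes over continuous features has no effective smoothing parameter
(Laplace smoothing touches only categorical likelihoods), so its grid is a
single row. CV accuracy is the mean held-out accuracy of the best
combination, which is then refit on all training samples. All fold layouts
and fits derive deterministically from the seed; identical data + config +
seed reproduce results bit-for-bit.

**Initial model selection.** The smallest gene-set level whose best CV
accuracy is within `tolerance` (default 0.005 absolute) of the global best
wins — accuracy parity is spent on panel size. Within the level, ties
break by fixed algorithm preference (rf, svm, cart, nb), then smaller
$\alpha$.

**Importance and reduction.** Only the random forest exposes per-feature
mean-decrease-in-Gini importances. A gene's importance is the *sum* over
the $n-1$ pair features containing it (a gene informative in many pairings
should outrank one informative in few; mean aggregation is available).
The protected set is located by the largest consecutive drop in the sorted
importance sequence — on reference-like importance profiles this separates
a high group of seven from a low group of six. Reduction then removes the
lowest-ranked unprotected gene, retrains with the identical protocol, and
stops when accuracy falls more than `drop_tolerance` (default 0.005) below
the running best. The *initial* ranking fixes the removal order
throughout (re-ranking after each removal is available via `rerank =
TRUE`); the final choice is the fewest-gene candidate within
`drop_tolerance` of the best accuracy seen — the selection rule that makes
an 11-gene model at parity beat a 12-gene model that is 0.0002 better.

**Panel naming note.** The shipped 11-gene panel contains FGFR4 (the
growth-factor-signalling member, rank-1 Her2E gene in the reference
table); one published listing of the final panel prints "FGFR1" instead,
but every other occurrence — the reference ssDEG table, the first-level
subset, the functional annotation, and 13 − {GRB7, KRT14} — yields FGFR4,
so the panel ships with FGFR4.

**Ensemble prediction.** One member model per slack margin (seven by
default) over one panel; features are rebuilt at each member's $\alpha$
and the final call is the unique modal subtype of the hard votes. A tied
mode yields `Ambiguous`, which downstream scoring always counts as
incorrect. Votes are counted as hard labels, not averaged probabilities
(probability averaging would almost never produce an exact tie and would
silently change the ambiguity semantics); the members are refit on
training data only, never on training + test. No fitted weights ship with
the package — none are publishable in portable form — so users train
member models on their own or synthetic cohorts against the shipped panel
structure.

**Evaluation.** Accuracy, Cohen's $\kappa$ with the classical asymptotic
standard error $\sqrt{p_o(1-p_o)/(n(1-p_e)^2)}$ for a 95% CI, and a
confusion matrix in which `Ambiguous` forms an extra prediction row with
no truth column while staying in the accuracy denominator. Scoring with
`exclude_normal_like = TRUE` drops samples whose *truth* is Normal-like
(the contested subtype, plausibly normal-tissue contamination) and leaves
all remaining cells untouched.

## Input handling

Expression files are delimited text, genes in rows; log2-encoded files are
decoded as $2^x - \text{floor}$ on read (floor 0 by default, 0.1 to invert
a $\log_2(\text{FPKM}+0.1)$ encoding exactly) because all downstream math
is defined on the linear scale. Probe-level arrays collapse to gene level
by the per-gene, per-sample maximum: the per-sample rule depends only on
the sample's own measurements, preserving the classifier's
cohort-independence; selecting one globally maximal probe per gene is
available as `"global_max_probe"` for comparison. Collapsed rows are
sorted by gene symbol so the result is invariant to probe row order.
Missing panel genes are an error naming the genes — never silent
imputation.

## The synthetic cohort generator

`simulate_subtypes()` draws, per gene and sample,
$x = \text{baseline}_g + \delta_g d_g [t = \text{subtype}(g)] +
\mathcal{N}(0, \sigma)$ on the log2 scale and emits
$\max(0, 2^x - 1)$ on the linear scale, so PGERs recover log2-scale
differences approximately. Defaults are chosen once as the study
conditions: class sizes 76/50/194/105/7 mirror a realistic discovery
cohort with Normal-like as the characteristic rare class; baselines are
uniform on [4, 9] log2 units (RPKM-like magnitudes); noise is log-normal
with $\sigma = 0.7$ (continuous RPKM-like values are what the classifier
consumes, so a count model would add realism the method never sees);
marker shifts default to $\delta = 2$ log2 units with directions mirroring
marker biology (ERBB2 up in Her2E, MLPH down in Basal-like, ...). The
default marker map leaves Normal-like markerless (optionally a half-effect
SFRP1), reproducing that subtype's instability.

The generator emulates: five-class mean structure, per-gene baselines,
log-normal noise, rare classes, probe-level duplication and log2 encodings
(via the fixture suite). It does **not** emulate gene–gene correlation,
platform/batch effects, graded within-subtype heterogeneity, or
compositional effects of real RNA-seq. Passing tests therefore demonstrate
that the pipeline's machinery recovers planted structure under its own
model assumptions — not that the shipped panel attains any particular
accuracy on real cohorts, which would require the original training data.

## Problem sizes and test design

The suite validates algebraic identities (antisymmetry, the soft-threshold
identity, $\alpha$-shrinkage) as randomized property tests; statistical
primitives against independent brute-force oracles (full enumeration for
the exact rank-sum p, step-up BH, the two-rater $\kappa$ formula); and the
pipeline on synthetic cohorts sized 60 samples per class with CV repeats
of 1–2 and forests of 150–200 trees — sizes chosen so the whole suite
runs in well under a minute while keeping planted-marker recovery
deterministic at the chosen effect sizes ($\delta = 3, \sigma = 0.5$ for
the screen; $\delta = 2, \sigma = 0.7$ for training). The acceptance
script reruns the same quantities from scratch at the same sizes.

## Known limitations

- The reported CV accuracy of the best hyperparameter combination is an
  optimistic estimate of generalisation (selection over the grid); the
  held-out split exists for honest evaluation.
- With few CV repeats the stepwise reduction is conservative: accuracy
  fluctuations of order 1% can trip the 0.005 stopping tolerance before
  all noise genes are removed. More repeats stabilise the path.
- The slack margin grid includes $\alpha = 1$ (a full log2 unit), which
  zeroes most small ratios; its member often behaves like a coarse,
  high-bias voter. The grid is a package constant but overridable.
- Cohen's $\kappa$ CI uses the simple asymptotic SE, adequate at the
  sample sizes scored here; exact or bootstrap intervals are out of scope.
- `Ambiguous` calls are rare with seven voters and five classes but are
  treated as first-class outcomes everywhere (extra confusion row, always
  incorrect).
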