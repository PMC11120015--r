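---
title: "NPULUD: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{NPULUD: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npulud)
```

## The problem

Positive-unlabeled (PU) learning arises when a binary classification task
provides confirmed positive instances and a pool of unlabeled ones, but no
confirmed negatives — screening registries, fraud lists, presence-only
observations. Treating the unlabeled pool as negative biases any standard
learner; ignoring it discards most of the data. NPULUD resolves the tension
in two stages: it first completes the labels by a deliberately conservative
nearest-neighbor rule, then fits an ordinary entropy-based decision tree on
the completed data.

## Stage 1: unanimous-vote nearest-neighbor relabeling

The data are D = P_L + U (labeled positives plus unlabeled instances;
benchmark datasets may also carry labeled negatives, which pass through
untouched). For each unlabeled x the k nearest neighbors N_k(x) are found in
all of D, excluding x itself. x becomes a *strong positive instance* — and is
relabeled positive, joining P_UL — exactly when all k neighbors are observed
positives. Any negative **or unlabeled** neighbor breaks unanimity and x is
assigned negative (N_UL). Compared with majority-vote k-NN, the unanimous
rule trades recall of hidden positives for precision: a point is promoted
only from a dense, purely positive neighborhood.

Assumptions this stage leans on:

* *Smoothness*: nearby instances share labels, so a fully positive
  neighborhood is strong evidence of a positive.
* *Labeled positives are representative* (selected roughly at random from
  the positives, the usual "selected completely at random" reading of PU
  data): hidden positives then tend to sit near labeled ones.
* *Unlabeled density matters*: because unlabeled neighbors break unanimity,
  the rule becomes more conservative as the unlabeled fraction grows. This
  is intentional — an unlabeled neighbor is not evidence of positivity — and
  its quantitative consequences are analyzed under "Limitations".

Distances are heterogeneous Euclidean: numeric features contribute squared
differences divided by the feature's observed range (min–max normalization,
the default, makes features with different units commensurable); categorical
features contribute 0 on a match, 1 on a mismatch; any comparison with a
missing value contributes the maximal 1. A zero-range numeric feature
carries no information and contributes 0 — except through missingness,
which still counts.

Decisions are made in a single pass over U using only the original observed
labels of D. Newly promoted positives never feed back into later neighbor
queries: cascading would make the outcome depend on processing order and
amplify early mistakes. As a consequence the result is invariant to the
storage order of instances.

Tunable parameters:

| parameter | default | meaning |
|---|---|---|
| `k` | 3 | neighborhood size; larger k demands unanimity over more votes, shrinking the strong-positive set monotonically |
| `pool` | `"all"` | neighbor pool; `"positives"` restricts the search to labeled positives, under which unanimity holds vacuously and every unlabeled point is promoted — exposed because the method's narrative description mentions distances to the nearest positives, but `"all"` is the operative rule |
| `normalization` | `"minmax"` | `"none"` uses raw differences, appropriate when features already share a scale |

## Stage 2: the entropy decision tree

The completed data P_L + P_UL + N_UL train a C4.5-style tree. Node impurity
is Shannon entropy in bits, H = −Σ R_i log2 R_i with 0·log2 0 = 0. A
candidate split into children D_1 … D_v is scored by information gain
(parent entropy minus size-weighted child entropy, always non-negative) or,
by default, by the gain ratio: gain divided by the entropy of the child-size
distribution. The gain-ratio denominator penalizes many-way splits; we apply
the standard C4.5 guard of ranking by ratio only among candidates whose gain
reaches the average gain of all positive-gain candidates, because otherwise
a split shaving off one or two instances has nearly zero split information
and an arbitrarily inflated ratio, producing needlessly deep trees even on
cleanly separable data.

Numeric features propose binary thresholds at midpoints of consecutive
distinct values; categorical features propose one multiway split over their
observed categories and are used at most once per path (a repeat split on
the same categorical feature cannot gain). Growth stops when a node is
pure, smaller than `2 * min_leaf` (default `min_leaf = 2`), at `max_depth`,
or when no candidate has positive gain. There is no pruning: `min_leaf`
guards the degenerate splits, and the intended use — small-to-moderate
tabular data — tolerates the extra variance of an unpruned tree.

Deterministic tie rules, chosen once so results are exactly reproducible:

* neighbor ties at equal distance: smaller instance id first;
* split-score ties: smaller feature index, then smaller threshold;
* leaf class ties: parent majority, then positive;
* missing value at a split (training or prediction) and unseen categories:
  follow the child with the most training instances.

## The evaluation protocol

`run_npulud_cv()` reproduces the benchmark protocol: a fully labeled
dataset is masked **once** — `round_half_up(ratio * n)` instances drawn
uniformly regardless of class lose their label — then split into stratified
folds; per fold, the training portion is relabeled, a tree is built and the
held-out fold predicted. Predictions are always scored against the retained
*true* labels: scoring against observed labels would make accuracy
undefined on masked instances. Stratification uses true labels too; this is
evaluation-side information only and never reaches training. Masking is
fixed per dataset rather than redrawn per fold, so every fold of one run
sees the same PU problem. `ratio_sweep()` repeats the procedure over
masking ratios (default 5–20%) with shared fold seeds so that only the
masking fraction varies.

Metrics are the four standard confusion-matrix ratios (ACC, PR, R, FM), with
zero-denominator cases reported as 0 and flagged rather than NaN. Paired
per-dataset comparisons use a two-sided Wilcoxon signed-rank test: zero
differences are discarded, absolute differences receive midranks, and for up
to 25 effective pairs the p-value is **exact**, computed by dynamic
programming over the conditional null (all 2^n sign assignments of the
observed, possibly tied, ranks equally likely). Base R's `wilcox.test()`
falls back to a normal approximation whenever ties occur; the DP removes
that limitation and matches `wilcox.test` exactly on tie-free cases (this
equivalence is part of the test suite). Beyond 25 pairs a tie-corrected
normal approximation is used. Column means of benchmark tables are held at
full precision internally and rounded half-up to two decimals only for
presentation.

## What the synthetic generators emulate — and what they do not

`generate_gaussian_pu()` draws class-conditional isotropic Gaussians whose
centroids lie `separation` within-class standard deviations apart, optional
class-conditional categorical features, and masks labels at `mask_ratio`
(default 5%, the benchmark protocol's headline setting; defaults n = 200,
two numeric features, balanced classes, separation 6). One seed drives
feature sampling and a derived seed the masking, so each part can be
regenerated independently. These are calibration fixtures: real screening
data are not isotropic, classes are rarely balanced, and label selection is
rarely uniform. Passing tests on these fixtures demonstrates correctness of
the machinery under known truth, not performance on any particular real
dataset.

`generate_grid_toy()` scales the packaged 20-instance example while
preserving its geometry: scale > 1 adds jittered copies (±0.1 on a unit
grid) of the labeled positives plus masked copies of the true negatives,
keeping class balance and never crossing a decision boundary. By
construction every masked instance remains recoverable by the unanimous
rule and the relabeled data stay separable by a depth-2 tree; the suite
asserts both at several scales.

Test and acceptance runs use problem sizes of 60–1000 instances with
10–50 masked labels and 20 replicate seeds where rates are averaged; these
sizes give the suite exhaustible oracles (full-sort neighbor search,
complete split enumeration) while keeping each check well under a second.

## Limitations

* **Unlabeled neighbors cap recovery.** A hidden positive is promoted only
  if none of its k neighbors is itself unlabeled. Under uniform masking of
  a fraction m, a masked positive's neighbors are masked with probability
  ≈ m each, so even with perfectly separated classes the expected recovery
  of masked labels is about 1 − (fraction positive) · (1 − (1 − m)^k) — for
  k = 3, m = 0.05 and balanced classes, roughly 0.92–0.94, with substantial
  seed-to-seed variance when only a handful of labels are masked (10 masked
  labels quantize recovery to steps of 0.1). The package reports recovery
  averaged over replicate seeds for this reason. The effect grows with the
  masking ratio: the unanimity rule is conservative by design, converting
  hidden positives into training negatives rather than risking false
  promotions.
* **Label noise from stage 1 propagates.** Masked positives assigned
  negative become mislabeled training points; the unpruned tree will fit
  them. On separable data this costs isolated leaves; on noisy data it can
  cost more, and a pruned or depth-capped tree (`max_depth`) may be
  preferable.
* **Exhaustive neighbor search** is O(n²) by contract — correct and
  auditable, not fast. Datasets beyond ~10^5 instances need an index this
  package deliberately does not provide.
* **Binary classes only**; multi-class PU learning is out of scope.
* The shipped benchmark tables are published summary results used as inputs
  to the aggregation and comparison helpers; the per-dataset values depend
  on external data and preprocessing not reproduced here, and this package
  makes no claim of reproducing them from raw data.
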