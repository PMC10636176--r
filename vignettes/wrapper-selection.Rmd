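---
title: "Grey wolf wrapper feature selection: model, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grey wolf wrapper feature selection: model, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the method

`wolfselect` addresses wrapper feature selection for classification: given a
labelled table with `d` numeric features, find a small subset of columns on
which a fixed classifier performs well. The search is a grey wolf optimizer
(GWO) — a swarm metaheuristic in which the three best solutions found so far
(alpha, beta, delta) attract the remaining agents through stochastic
"encircling" updates — together with a modified variant (MGWO) that changes
three things at once, each independently switchable:

1. **Exponential decay of the exploration parameter.** The coefficient
   vector `A` is drawn uniformly from `[-a, a]` per component; `|A| > 1`
   sends an agent away from a leader (exploration), `|A| < 1` pulls it in
   (exploitation). Standard GWO decays `a = 2 (1 - t / t_max)` linearly; the
   modified schedule is `a = 2 exp(-t s / t_max)` with `s` the swarm size,
   so with the default protocol (`s = 5`, `t_max = 20`) exploration
   effectively ends within the first few iterations.
2. **Variable leader weights.** Instead of averaging the three
   leader-driven candidate positions equally, the aggregation uses
   `w1 = cos(theta)`, `w2 = sin(theta) cos(phi) / 2`, `w3 = 1 - w1 - w2`,
   with `phi = arctan(it) / 2` and `theta = (2/pi) arccos(1/3) arctan(it)`.
   At the first update the alpha dominates (`w ~ (0.82, 0.27, -0.08)`); as
   `it` grows all three converge to `1/3`. The residual `w3` is negative for
   `it = 1`, so the combination is affine rather than convex there; we keep
   the schedule exactly as defined (the aggregate is clamped to bounds
   afterwards) and expose `clamp_w3_nonneg` for users who want a strictly
   convex combination. The iteration index is 1-based at the first update:
   the weights are meant to change along the run, which rules out the
   constant-"total iterations" reading.
3. **Chaotic initialization.** Initial coordinates come from per-agent
   logistic maps `x -> 4 x (1 - x)`, seeded uniformly on (0.01, 0.99) away
   from the map's degenerate points {0, 0.25, 0.5, 0.75, 1}, with 100
   burn-in iterates. The map's invariant density is beta(1/2, 1/2), so the
   initial swarm concentrates near the faces of the unit hypercube.

Candidate subsets are scored by the wrapper fitness

```
fitness = alpha_w * error + (1 - alpha_w) * |S| / d,      alpha_w = 0.9
```

where `error` is the misclassification rate of a k-nearest-neighbour
classifier (`k = 5`, Euclidean distance) under stratified 10-fold
cross-validation restricted to the masked columns, and `|S|` is the subset
size. Lower is better; at the defaults one extra feature costs `0.1 / d`
fitness units, so among equally accurate subsets the smaller wins.

## From continuous positions to masks

A transfer function maps each coordinate to (0, 1):
`x_s = 1 / (1 + exp(-10 (x - 0.5)))`. A uniform draw `R` per coordinate then
yields a bit. Two directions of the comparison are implemented:
`"as_printed"` sets the bit when `R >= x_s` (the piecewise rule exactly as
published, under which a high coordinate means a *low* selection
probability) and `"conventional"` sets it when `R < x_s`. The raw
`binarize()` operation defaults to `"as_printed"` for fidelity; the
selection driver defaults to `"conventional"`, for the reason below. Empty
masks are repaired by switching on one uniformly chosen bit rather than
penalized, which keeps the fitness scale intact.

### Swarm representation: the design that was genuinely open

The published equations describe both a continuous position per wolf and a
binary solution per wolf without wiring the two together. Two defensible
wirings exist, and we implemented both:

* `representation = "mask"` (default): the agent's position *is* its binary
  mask. The leader-driven arithmetic produces a continuous intermediate,
  which is clamped to the unit cube and re-binarized into the next mask.
  This is the standard binary-GWO construction. A converged swarm sits on
  hypercube corners, so it genuinely exploits the neighbourhood of good
  masks. Under this wiring the `"as_printed"` transfer direction would
  invert a converged mask at every step (a corner coordinate of 1 maps to a
  selection probability near 0), which is why the driver pairs the mask
  representation with the `"conventional"` direction by default.
* `representation = "continuous"`: a real-valued position persists across
  iterations and a fresh stochastic mask is drawn from it at every
  evaluation. Mid-range coordinates re-roll their bits each time, so the
  search keeps sampling broadly and cannot concentrate on one mask. On very
  small spaces this behaves like an excellent random sampler: on a
  four-feature problem it matches exhaustive enumeration almost always.

Measured on the package's own synthetic data, the mask representation
yields smaller subsets and satisfies the tighter end-to-end checks at 500
features; the continuous representation is the stronger exact-optimum
matcher at `d <= 6`. Both are exported, tested, and documented by those
strengths.

### A structural note on subset shrinkage

In mask space the encircling distance `D = |C * Xp - X|` vanishes
identically when a leader bit and an agent bit are both 0, regardless of
the coefficients: deselected features are nearly absorbing, while selected
features keep being perturbed whenever `a` is large. Subset cardinality
therefore shrinks roughly in proportion to the time spent exploring. A
consequence we document honestly: under identical budgets the *standard*
schedule (which keeps `a > 1` for half the run) reaches equal or smaller
subsets than the modified schedule on easy synthetic data, where the
modified variant's early exploitation shows up in error rather than in
subset size. The package's multi-run benchmark reports both quantities so
users can see the trade-off on their own data.

## The classification pipeline

The end-to-end pipeline mirrors a deep-feature plant-disease classifier:
images (or a precomputed feature table) are split stratified 70/15/15 into
train/validation/test with a fixed seed; MGWO selects a mask **on the
training partition only**; an SVM (libsvm backend) is trained on the masked
training partition over a small grid (linear and radial kernels, cost in
{0.1, 1, 10, 100}) and the grid cell is chosen by validation accuracy; the
winner is scored exactly once on the test partition. The report carries the
confusion matrix, sensitivity/specificity/precision/accuracy/F1 as
percentages, and an ROC curve built by sweeping a threshold over the SVM
decision values. Multi-class inputs use the backend's one-vs-one
construction — `K (K - 1) / 2` pairwise machines — the standard count for
pairwise ensembles. The positive class defaults to `diseased` and is
configurable.

The default feature extractor is a deterministic image-statistics
projector (grid-block means and standard deviations per channel plus global
moments), which keeps the repository self-contained and every test
offline. Any `function(image_array) -> numeric` with a declared `width`
attribute can be plugged in instead — e.g. a wrapper around a pretrained
CNN's penultimate fully-connected layer (4096 features for the classic
8-layer architecture), the kind of embedding these workflows use in
production.

## What the synthetic generators emulate

* `make_tabular()` builds class-conditional Gaussian tables with a declared
  total centroid separation `class_sep * noise_sd` **split evenly across
  the informative columns** (offset `class_sep * noise_sd / n_informative`
  per column). The split matters: it makes each informative column a
  distinctly weaker classifier than the joint subspace, so the ground-truth
  subset is the genuine fitness optimum — with the full separation on every
  column, one column alone would classify perfectly and the subset-size
  penalty would correctly drop the rest, making "recover all informative
  columns" an incoherent target. Redundant columns are noisy linear
  combinations of informative ones; noise columns are label-independent.
* `make_feature_table()` emulates penultimate-layer activations: rectified
  Gaussian marginals (non-negative, unit within-class spread), with a
  class-mean shift of `class_sep` (default 1 sd) on a random informative
  fraction. The default effect size gives strong but imperfect
  separability, comparable to published deep-feature accuracies in the
  76–100% range. Class sizes can mirror real datasets (the worked examples
  use 159/77).
* `make_toy_images()` writes `root/<class>/*.png` trees of green-textured
  tiles; "diseased" tiles receive dark elliptical lesions at a Poisson
  rate (defaults: 0 healthy, 5 diseased). The classes are separable from
  intensity statistics, which is exactly what the default extractor senses.

What these generators deliberately do **not** model: feature correlations
of real deep embeddings, heteroscedastic noise, class imbalance beyond the
declared counts, and photo-realistic leaf structure. Passing tests
demonstrate that the machinery recovers *planted* signal under clean
assumptions, not that it matches the published accuracy tables, which would
require the original images and unpublished seeds.

## Numerical choices and degenerate inputs

* Features are min–max scaled to [0, 1] per cross-validation training fold
  (parameters learned on training folds only) before distances are
  computed; unscaled Euclidean distance would be dominated by wide-range
  columns.
* KNN class ties break deterministically: smallest summed neighbour
  distance among the tied classes, then lowest class index.
* Leader ranking ties break by smaller mask cardinality (aligned with the
  feature-minimization objective), then by agent id.
* If a class has fewer members than the fold count, the fold count drops to
  the minimum class size with a warning. Single-class data, fewer than two
  feature columns, and empty class folders are errors with explicit
  messages.
* Zero denominators in confusion-matrix metrics return 0 with a warning.
* One user seed drives everything through fixed substreams (initialization,
  fold assignment, binarization, splits), so components are independently
  reproducible and a whole run is bit-reproducible.

## Problem sizes used in the shipped checks

The package's own test protocol uses the published run configuration
(5 agents, 20 iterations, 20 independent runs, `alpha_w = 0.9`, `k = 5`,
10 folds) at sizes chosen so the whole suite runs in minutes on one core:
the controlled recovery dataset has 200 samples with 2 informative + 8
noise columns at total separation 6 sd; exhaustive-oracle comparisons use
4–6 columns (15–63 candidate masks); the pipeline check uses a 236-row,
500-column feature table with 20 informative columns; the continuous
engine check minimizes the 10-dimensional sphere function with 30 agents
and 200 iterations.

## Known limitations

* The wrapper cost is one cross-validated KNN fit per distinct mask; the
  driver memoizes masks within a run, but very high-dimensional tables make
  each evaluation itself expensive.
* The weight schedule is used exactly as defined, including the negative
  `w3` at the first update; enabling `clamp_w3_nonneg` changes the
  trajectory slightly.
* The multi-run benchmark reports the same cross-validated accuracy used
  inside the fitness (no second held-out split), so its accuracy column
  carries the optimistic bias inherent to wrapper selection; the pipeline,
  by contrast, reports held-out test metrics.
* Published absolute benchmark numbers are shipped as reference data for
  the reporting utilities, not reproduced computationally.
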