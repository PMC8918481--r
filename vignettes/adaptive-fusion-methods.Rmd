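---
title: "Adaptive-fusion ensembles for imbalanced classification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive-fusion ensembles for imbalanced classification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imbfuse)
```

## The problem

When one class outnumbers the other by a factor of 3–30 — the regime of
most clinical and benchmark imbalanced datasets — ordinary classifiers
drift toward the majority class: the decision boundary is placed where
majority density, not class structure, dictates. `imbfuse` attacks the
problem at three levels at once:

1. **Representation.** A linear map $L$ is learned so that distances in the
   transformed space $x \mapsto Lx$ respect class structure, with an
   imbalance-aware weighting that keeps the minority class from being
   ignored during metric learning itself.
2. **Data.** Inside each ensemble member's feature subspace the minority
   class is rebalanced by SMOTE interpolation, so every base classifier
   trains on equal class counts.
3. **Fusion.** Members do not vote equally: a genetic algorithm assigns
   each classifier a weight by maximizing the AUC of the fused score on a
   held-out validation slice.

## The weighted large-margin objective

The transform is a large-margin nearest-neighbor (LMNN) variant. Fix for
every anchor $x_i$ its $k_t$ nearest same-class neighbors in the original
space (its *target neighbors*, default $k_t = 3$). The classic LMNN loss
pulls targets in and pushes every different-class *impostor* $x_l$ beyond a
unit margin:

$$
f(L) \;=\; \sum_{i,j} \lVert L(x_i - x_j)\rVert^2
\;+\; \sum_{i,j}\sum_{l} \bigl[\,1 + \lVert L(x_i - x_j)\rVert^2
- \lVert L(x_i - x_l)\rVert^2 \bigr]_+ .
$$

On imbalanced data the sums are dominated by majority anchors, so each
anchor's pull and push terms are multiplied by a weight

$$
w_i \;=\; \frac{\delta_i}{\lvert N_c\rvert \cdot d(x_i, \bar X_c)},
$$

with three deliberate factors:

* $1/\lvert N_c\rvert$ — the anchor's class size. Summed over a class this
  normalizes each class's total contribution, so the minority class is not
  drowned out; per anchor, minority weights exceed majority weights by
  exactly the imbalance ratio when the other factors match.
* $\delta_i = \delta_n^i + \delta_p^i$ — a boundary emphasis.
  $\delta_n^i$ is the inverse mean distance from $x_i$ to its $k$ nearest
  majority samples and $\delta_p^i$ likewise for the $h$ nearest minority
  samples (defaults $k = h = 5$). Samples close to *both* classes — the
  decision-boundary region — get large $\delta_i$.
* $1/d(x_i, \bar X_c)$ — outlier damping. $\bar X_c$ is the mean of the
  anchor's own class; a point far from its class center is likely noise and
  is down-weighted. We use the class *mean* as the center: a raw sum over
  class members scales with class size and is not a geometric center, and
  the class-size effect is already carried explicitly by
  $\lvert N_c\rvert$.

All distances that can vanish (duplicated points, a sample exactly at its
class mean) are clamped below by $\varepsilon = 10^{-12}$, keeping every
weight finite and strictly positive.

Two boundaries of the design are worth stating. The anchor's weight $w_i$
multiplies both its pull and its push terms; the impostor's own weight does
not enter. And the impostor set is the *full* enumeration of
different-class samples per target pair — no margin-violator mining — which
is exact and affordable at the sample sizes this package targets (up to a
few thousand rows).

## Optimization

The loss is piecewise quadratic in $L$ and its exact subgradient is

$$
\nabla f = 2L\Bigl(\textstyle\sum_{(i,j)} w_i C_{ij}
 + \sum_{\text{active}} w_i (C_{ij} - C_{il})\Bigr),
\qquad C_{ab} = (x_a - x_b)(x_a - x_b)^{\!\top},
$$

where a triplet is active iff its hinge argument is strictly positive
(triplets exactly at the kink contribute nothing). We run plain gradient
descent from the identity (truncated to `output_dim` rows if a low-rank map
is requested) with per-iteration step halving: a step that would increase
the loss is halved and retried, up to 20 times, so the accepted loss
sequence is non-increasing *by construction* — the property the test suite
asserts exactly, not approximately. Iteration stops at `max_iters`
(default 200), when no halved step improves, or when the relative
improvement drops below `min_rel_improvement` (default $10^{-6}$). The fit
uses no randomness, so identical data and configuration give a bit-identical
map. Defaults: `learning_rate` $10^{-3}$ on standardized features,
margin 1.

Features are standardized internally by default (training statistics only;
the returned transform replays them on new data). LMNN-family objectives
are scale-sensitive — with raw features, one wide column can dominate every
distance — and the fixed unit margin needs a comparable distance scale to
act on. Zero-variance columns get scale 1, i.e. they are centered but not
divided.

Target neighbors, weights and triplets are computed once in the original
(standardized) space and stay fixed; dynamic impostor re-mining is
deliberately out of scope. Nearest-neighbor ties are broken by lower row
index, which keeps every stage exactly reproducible.

### What the unit margin implies — a known limitation

The margin constant couples the objective to the data's distance scale.
When the typical squared-distance gap between an anchor's nearest impostor
and nearest target already exceeds 1 (high dimension, well-spread data),
most hinges start inactive, the pull term dominates, and the optimal map
*contracts* the space mildly until hinge activation balances the pull. The
contraction is nearly isotropic, so it shrinks absolute distance gaps while
still improving the *relative* geometry. For this reason the package
exposes two diagnostics: `mean_anchor_margin()` (nearest-impostor minus
nearest-same distance, scale-dependent) and `mean_separation_ratio()`
(their ratio, scale-invariant). On overlapping synthetic data
(`class_separation = 2`, 2 informative + 4 noise dimensions, 150/30
samples) the learned map typically raises the separation ratio — the
`separation_ratio_gain` that `scripts/acceptance.R` recomputes, and the
property the test suite asserts across generator seeds — while the
absolute margin typically *falls*: the contraction at work, not a failure
to reshape the space. Downstream classification is unaffected: AUC is
invariant to a global rescaling of the feature space.

## SMOTE rebalancing

Each synthetic minority point is $x_i + (x_n - x_i)\,r$ with $r \sim
U[0,1]$, $x_i$ a minority seed and $x_n$ one of its `k_neighbors` (default
5, the classical choice) nearest minority neighbors *in the subspace being
balanced* — the ensemble applies SMOTE after the transform and the column
projection, so neighborhoods are those the member actually sees. Seeds
cycle through the minority class in a shuffled order, so every minority
sample contributes before any repeats; the quota is exactly
$n_{maj} - n_{min}$, giving equal class counts. Original rows are preserved
verbatim and first, and a provenance log (seed index, neighbor index, $r$
per synthetic row) makes the segment-membership property directly
checkable. When the minority class has fewer than `k_neighbors + 1`
members, the neighbor count is capped with a warning rather than failing.

## Subspace ensemble and weighted fusion

The transformed data is projected onto $N$ random column subsets (default
$N = 15$), each of size $M = \max(1, \lfloor 0.7\,r \rfloor)$. Subsets are
drawn uniformly without replacement within a subspace and independently
across subspaces; duplicate subspaces are possible and harmless — they only
duplicate a member. Each member is a linear max-margin classifier
(soft-margin linear SVM, cost 1) trained on its SMOTE-balanced projection;
its score is the signed distance to the hyperplane, oriented so larger
means more minority-like.

Fusion is a dot product of member *scores* — not hard labels — with a
simplex weight vector: AUC evaluation and the AUC fitness both need a
ranking, which hard votes cannot provide. The hard prediction thresholds
the fused score at zero.

## Genetic weight search

A gene is a vector in $[0,1]^N$; as voting weights it is normalized by its
sum (an all-zero gene falls back to uniform). The search is deliberately
minimal: random parent pairs; single-position crossover (the two parents
exchange exactly one coordinate) with probability 0.9; per-position
mutation to a fresh uniform draw with probability 0.1; and elitist
replacement — a child replaces the current *worst* population member only
on strict fitness improvement. Elitism makes the best-fitness trajectory
non-decreasing by construction, another exactly-assertable invariant.
Defaults: population 30, 30 children per generation, at most 100
generations, early stop after 25 stalled generations.

Fitness is the AUC of the fused score on a stratified 25% slice of the
training partition that is held out from *both* metric learning and member
training. Scoring the members on their own training data would reward
overfit members with inflated weights; the held-out slice prices each
member by generalization. Both the fraction and the policy are
configurable (`ga_fraction`, `use_ga`).

## Evaluation protocol

`repeated_cv_evaluate()` runs 5 repetitions of stratified 5-fold
cross-validation by default. Stratification deals each class round-robin
onto folds in shuffled order, so per-fold class counts deviate by at most
one sample. The full pipeline — transform, subspaces, SMOTE, members, GA —
is fit on each training partition only; the held-out fold is scored and its
AUC recorded. AUC is the rank-based Mann–Whitney form with midrank ties,
equal to the probability that a random minority sample outscores a random
majority sample. The report gives mean ± population standard deviation
over all run-folds, plus per-run aggregates, since "±" conventions differ
across papers. Folds whose test partition happens to contain a single
class (possible at extreme imbalance) are recorded as missing and excluded
with a warning rather than failing the experiment.

One master seed drives everything: fold seeds, subspace draws, SMOTE
streams, the GA, and the internal validation split are all derived from it
by a fixed integer-folding scheme (`derive_seed()`), so any experiment is
reproducible from a single number, and repeated evaluation is bit-identical.

## The synthetic generator — and what it does not emulate

`generate_synthetic()` draws the majority class from an isotropic
unit-variance Gaussian at the origin of the informative subspace and the
minority class at distance `class_separation` (in within-class SD units)
along the first informative axis; noise dimensions are standard Gaussians
for both classes. This gives direct control over the imbalance ratio, the
overlap and the fraction of uninformative directions — the three axes that
matter for this method — and it makes oracle checks cheap (a 1-NN
classifier must be near-perfect at separation 8, and is).

It deliberately does *not* emulate multimodal classes, correlated features,
heavy tails, label noise, or discrete attributes. Passing tests on this
generator therefore demonstrate the pipeline's contracts and its behavior
under controlled imbalance and overlap — not performance claims on any real
dataset.

Problem sizes used by the test and acceptance workloads were chosen to
exercise every stage at full strength while staying desk-sized: the
end-to-end reference task uses 500 majority / 50 minority samples
(imbalance ratio 10, inside the 3–30 regime of the standard benchmarks)
with 2 informative + 8 noise dimensions at separation 3; metric-learning
property checks use 100–150 majority samples; oracle comparisons use
n ≤ 30 where brute-force enumeration is exact and instant.

## Numerical choices, edge cases

* Distance clamps at $\varepsilon = 10^{-12}$; weights are therefore always
  finite and positive, even with duplicated rows.
* Remainder samples in stratification land on folds in shuffled order —
  no fold is systematically larger.
* `read_delimited()`/`read_keel_dat()` map the *rarer* raw label to class 1
  (the package-wide minority-positive convention); an exact tie is broken
  toward the lexicographically larger label, which makes the KEEL
  writer/reader pair an identity even on balanced files.
* Subspace size uses the floor rule with a minimum of 1 feature.
* The serialized form of an ensemble stores each member as its effective
  hyperplane $(w, b)$; this is exact for the linear base classifier and is
  verified against the live scorer at write time.

## Limitations

* Binary classification only; the voting and AUC machinery is two-class.
* The full impostor enumeration is quadratic in class sizes per target
  pair; beyond roughly $10^4$ samples, impostor mining would be needed.
* The unit margin's scale coupling (discussed above) means the learned map
  usually contracts distances on well-spread data; use
  `mean_separation_ratio()` when judging the geometry, and AUC when judging
  the pipeline.
* The GA is a heuristic: it guarantees monotone best fitness, not a global
  optimum, and its value over uniform weights grows with member-quality
  spread.
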