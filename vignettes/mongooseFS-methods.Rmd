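---
title: "Binary dwarf mongoose optimization for wrapper feature selection: methods and design"
author: "mongooseFS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Binary dwarf mongoose optimization for wrapper feature selection: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mongooseFS)
```

## The problem

High-dimensional classification data — microarray gene-expression panels are
the canonical case — pair tens of samples with thousands to tens of thousands
of features, of which only a small core carries class signal. A *wrapper*
feature-selection method searches the space of feature subsets directly,
scoring each candidate subset by the predictive error of a classifier trained
on it. With $D$ features there are $2^D$ subsets (`searchSpaceSize(1000)` is
about $1.07 \times 10^{301}$), so the search needs a capable combinatorial
optimizer. mongooseFS drives that search with a binary adaptation of the
dwarf mongoose optimization (DMO) metaheuristic.

## The continuous optimizer

DMO is a population-based minimizer modelled on the social foraging of dwarf
mongooses. A population of $n$ agents (default 10) holds positions
$X_i \in [\mathrm{lb}, \mathrm{ub}]^D$; $\mathit{bs}$ of them (default 3) are
*babysitters*, temporarily sidelined, and the remaining $n - \mathit{bs}$
form the foraging (alpha) group. Each iteration:

1. **Evaluation and alpha selection.** Forager fitnesses are computed and an
   alpha is drawn by roulette. The fitness-proportional rule
   $\alpha_i = \mathit{fit}_i / \sum_j \mathit{fit}_j$ is stated for the
   original algorithm, but under a minimization objective it assigns the
   *highest* selection probability to the *worst* agent. The package
   therefore defaults to inverse-fitness weights
   $w_i = 1/(\mathit{fit}_i + \varepsilon)$, $\varepsilon = 10^{-10}$, so the
   alpha leans toward the fittest agent, as the algorithm's narrative
   requires; the literal proportional rule remains available as
   `alphaMode = "literal"` for fidelity experiments.
2. **Foraging.** Every forager proposes a candidate food position
   $X_i + \phi \cdot \mathit{peep}$ with $\phi \sim U[-1, 1]$ drawn
   independently per dimension (per-dimension noise is required for movement
   in all coordinates) and $\mathit{peep}$ the alpha's vocalization
   coefficient (default 2.0; no reference value is stated for it, and 2.0
   puts candidate steps on the scale of the unit box). The candidate
   replaces the incumbent only if strictly better. This *greedy acceptance*
   is a design choice: it makes the objective trace of each agent monotone
   and, together with best-ever tracking, makes the reported convergence
   history provably non-increasing.
3. **Sleeping mounds.** Each forager's normalized fitness change
   $sm_i = (\mathit{fit}_{new} - \mathit{fit}_{old}) /
   \max(|\mathit{fit}_{new}|, |\mathit{fit}_{old}|)$ (0 when both are 0) is
   computed from the candidate's fitness against the incumbent *before*
   acceptance — the observed change the score is meant to capture. Their
   mean $\varphi$ summarizes how much the population is still improving.
4. **Scouting.** Every forager moves relative to the movement vector, taken
   here as the $sm$-weighted mean position
   $M = \tfrac{1}{n}\sum_i sm_i X_i$ (the printed form
   $\sum_i (X_i \times sm_i)/X_i$ is dimensionally degenerate, so the
   weighted mean is the package's interpretation). If $\varphi$ increased
   over the previous iteration the move is exploratory,
   $X - \mathrm{CF}\cdot\mathrm{rand}\cdot(X - M)$, otherwise exploitative,
   $X + \mathrm{CF}\cdot\mathrm{rand}\cdot(X - M)$, with
   $\mathrm{rand} \sim U[0,1]$ per dimension and
   $\mathrm{CF} = (1 - t/T)^{2t/T}$ the collective-volatile factor shrinking
   from 1 to 0 over the run. The first iteration has no previous $\varphi$
   and takes the exploitation branch. A $\phi$ factor appears in one printed
   form of the scout update but not in the pseudocode listing; the package
   follows the listing. All moves are clamped to the box (boundary handling
   is otherwise unspecified).
5. **Babysitter exchange.** A counter $C$ increments once per iteration;
   when $C \geq L$ the $\mathit{bs}$ worst foragers are demoted and the
   babysitters re-enter foraging with re-randomized positions and discarded
   fitness ("reset fitness" is interpreted as *unevaluated* — a literal
   fitness of zero would be a perfect score under minimization). $L$
   defaults to $\mathrm{round}(0.6 \cdot D \cdot \mathit{bs})$ and is
   configurable; no increment rule or $L$ value is stated in the source
   description, so both are package choices, echoed in every output.

Elitism is global: the best position and fitness ever evaluated are retained
and reported, so `convergence()` traces are non-increasing for every seed
and objective.

A single seeded RNG stream drives a run, consumed in a fixed, documented
order (initialization, then per iteration: alpha draw, foraging noise, scout
noise, exchange redraws). Two runs with the same configuration and seed are
bit-identical; this is asserted in the test suite.

## The binary adaptation and the wrapper objective

Feature selection restricts solutions to $\{0,1\}^D$: bit $d$ selects
feature $d$. The optimizer searches the continuous unit box and each
position is *binarized* with the static threshold 0.5: a coordinate strictly
above 0.5 selects its feature. (The source description states the strict
form in its equation and "0.5 and above" in prose; the equation is
followed.) An all-zero mask cannot be scored; the default repair sets one
uniformly chosen bit (`repairPolicy = "random_one"`), and the alternative
`"penalty"` leaves the mask and scores it with the worst error 1.0.

The fitness of a mask is the classification error rate (CEE) of a
$k$-nearest-neighbour classifier ($k = 5$, Euclidean distance) under
stratified $k$-fold cross-validation ($K = 10$) on the training split:
misclassified instances divided by total instances, so accuracy
$= 1 - \mathrm{CEE}$. Protocol details the package fixes where the source
is silent:

* **Hold-out.** Each run first splits the data 80/20, stratified by class
  with per-class rounding (every class keeps at least one instance on each
  side). Feature selection sees only the 80%; the 20% measures validation
  accuracy, precision and F-measure of the final mask.
* **One fold assignment per run.** Folds are drawn once, stratified by
  class, and reused for every fitness evaluation. This makes the objective a
  deterministic function of the mask, so greedy acceptance and the monotone
  convergence guarantee are well-defined. Stratification matters: the target
  regime includes datasets with 50 instances over 4+ classes, where
  unstratified folds can lose a class entirely. When 10 folds are infeasible
  the fold count is reduced to the smallest class count with a warning.
* **kNN tie-breaking.** Distance ties go to the lower training-row index; a
  tied vote goes to the tied class whose nearest representative is closest.
  Fixed so that the objective is fully deterministic.
* **No feature scaling by default** (none is mentioned in the protocol being
  mirrored); optional z-score standardization, fit on each fold's training
  block only, is available via `standardize = TRUE` and is advisable for
  real expression data with heterogeneous feature scales.
* **Metrics averaging.** For binary problems precision/recall/F-measure
  refer to the positive class (the second factor level); for multiclass they
  are macro-averaged, with an unpredicted class contributing precision 0.
  The reference tables report single values without stating a scheme.

One line of the source pseudocode ("select a set of dimension rates using
tournament selection") is defined nowhere in the text and is deliberately
not implemented rather than guessed.

## The synthetic data generator

`makeSyntheticData()` emulates the benchmark regime the method targets: few
instances, $10^2$–$10^4$ features, 2–20 classes, a small informative core.
Labels are balanced up to rounding. Informative features are class-
conditional Gaussians with unit SD; the class centroids sit at the vertices
of a regular simplex scaled so each pair of centroids is `classShift` apart
in simplex coordinates, tiled across the informative features (for two
classes the per-feature means are $\pm\,\mathrm{classShift}/(2\sqrt 2)$).
The default `classShift = 3` makes single features weakly informative but
the 10-feature core strongly discriminative — separable, but not so
trivially that any mask works, which is the interesting regime for a
wrapper. Redundant features are random unit-norm linear combinations of the
informative block plus Gaussian noise (`redundancyNoise`, default SD 0.1);
all remaining features are i.i.d. standard Gaussian, independent of labels.
Feature order is randomly permuted and the ground-truth informative indices
travel with the dataset.

The generator is Gaussian for analytic transparency. Real microarray data
have heavy tails, batch structure and correlated noise that this model does
not reproduce, so green tests on synthetic data demonstrate the machinery
(the optimizer reduces the objective, recovers discriminative subsets,
reproduces bit-exactly) — not performance claims on any real benchmark
suite.

`toyFixture()` is a fixed 8x6 two-class table (two separating features near
$\pm 5$, four zero-mean noise features) for exact, enumerable regression
tests.

## The evaluation harness

`runBenchmark()` repeats `selectFeatures()` over independent runs (the
reference protocol uses 20), run $r$ seeded `baseSeed + r`, and aggregates
mean/SD of best fitness, mean validation metrics, the average number of
selected features and mean wall time, preserving all convergence histories.

`friedmanMeanRanks()` ranks algorithms within each dataset row (lower score
better, average ranks for ties) and averages ranks per algorithm. Missing
cells are ranked among the present entries of their row only — published
comparison tables in this literature contain missing cells without a stated
handling rule, so exact reproduction of any published mean rank is not
claimed.

`wilcoxonSignedRank()` mirrors the reporting format of SPSS-style paired
comparisons: zero differences dropped and counted as ties, average ranks on
$|d|$, separate negative/positive rank sums, and a normal-approximation
two-tailed p (tie-corrected variance, no continuity correction). Numerical
accuracy note: against exact sign-assignment enumeration (mid-p), the
asymptotic p is within 0.02 for every tie-free rank configuration at
$n \geq 9$, but deviates by up to about 0.03 at $n = 8$ — an intrinsic
limit of the approximation at that size, so exact enumeration is preferable
below $n = 9$. The test suite carries an enumeration oracle for exactly this
comparison.

## Problem sizes used in the shipped checks

The package's own tests and the acceptance script run, as their standard
workload, a 100-instance x 200-feature two-class generator dataset
(10 informative features, shift 3) with 10 agents, 3 babysitters and 50-100
iterations over 5-20 runs — large enough that the optimizer must genuinely
search (the all-features baseline is beatable but non-trivial), small enough
to iterate on quickly. Elitism/monotonicity checks run 20 seeds on the toy
fixture and a 60x80 synthetic dataset.

## Known limitations

* The movement-vector and alpha-selection rules are interpretations of a
  degenerate printed formula and a maximization-oriented rule respectively;
  both choices are flagged above and switchable where meaningful.
* kNN is the only wrapped classifier; alternative classifiers are out of
  scope.
* The Gaussian generator does not model microarray heavy tails or batch
  effects.
* `.mat` benchmark archives are not read directly; convert to CSV (header
  row `f0,...,f(D-1),label`) or ARFF.
* Wall-clock fields (`elapsed`, timestamps) are the only non-reproducible
  outputs; every statistical quantity is a pure function of the recorded
  seeds.
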