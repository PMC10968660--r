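---
title: "Metaheuristic wrapper feature selection: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metaheuristic wrapper feature selection: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaselect)
```

## The problem

Epidemiological surveys ask thousands of questions, most of them irrelevant
to any one outcome. When the outcome is a binary diagnosis — here,
sarcopenia, operationalized as handgrip strength strictly below 28 kg in men
or 16 kg in women — a classifier trained on the full questionnaire wastes
capacity on noise, and clinicians cannot act on a 700-item model. Feature
selection looks for a small subset of items that predicts the diagnosis as
well as, or better than, the full set.

`metaselect` treats subset selection as combinatorial optimization over
binary masks: bit *j* is 1 when feature *j* is included. Two metaheuristics
search this space — a genetic algorithm (GA) and harmony search (HS) — each
scoring candidate masks with a *wrapper* fitness: the mean accuracy of a
naive Bayes classifier under stratified 5-fold cross-validation on the
training partition. Filter baselines (correlation-based subset evaluation
with best-first search, and information-gain thresholding) and an exhaustive
small-*p* oracle anchor the comparison.

## Data model

A `survey_dataset` holds instances × features, each feature `nominal`
(category tokens) or `numeric`, with missingness as a first-class cell
state. Nothing in the package imputes: naive Bayes simply skips a missing
cell in both fitting and prediction, the entropy-based filters use
pairwise-complete rows, and decision trees use surrogate splits. Survey
items whose codes do not parse fully as numbers are treated as nominal;
no scaling, one-hot encoding, or other feature engineering is applied.
This keeps the pipeline faithful to raw survey exports, where ordinal codes,
ranges, and skip-pattern missingness make automated transformations risky.

Preprocessing mirrors common survey practice: features with five or fewer
non-missing responses are dropped, as are ID-like nominal columns (≥ 99% of
non-missing tokens distinct). The "five or fewer" rule counts non-missing
responses; the ID rule operationalizes "unique identifier" as a
distinct-fraction threshold, since near-unique free-text columns are as
useless as literal IDs.

Labelling by handgrip threshold drops records with missing grip or
unmappable sex (they are uncounted rather than guessed), and removes the
grip column itself from the feature set, so the classifier can never read
off the diagnosis. The boundary case — grip exactly at the threshold — is
negative, because the criterion is *strictly below*.

The 80/20 train/test split and the 5-fold CV are stratified. Per class, the
training partition receives exactly `floor(0.8 * n_c)` instances; with class
totals 2,564/3,924 this yields 2,051 + 3,139 training and 513 + 785 test
instances, matching the published bookkeeping exactly. Fold sizes per class
differ by at most one.

## The wrapper fitness

The fitness of a mask is the mean held-out accuracy of naive Bayes over a
stratified 5-fold partition fixed by a seed. Modelling choices:

* **Nominal likelihoods** use Laplace add-one smoothing over the category
  set observed in training for that feature: `P(v|c) = (count + 1) /
  (n_c + K)`. A category unseen in training gets the smoothed floor
  `1 / (n_c + K)`.
* **Numeric likelihoods** are a single Gaussian per (feature, class). The
  standard deviation is floored at `1e-6` of the feature's training range
  (absolute minimum `1e-9`) to avoid zero-variance singularities; the floor
  is a documented constant of this implementation, not a claim about any
  other toolkit's internal precision.
* **Missing cells** contribute nothing anywhere. A (feature, class) pair
  with no training observations contributes nothing at prediction for that
  class.
* **Posteriors** are computed in log space and normalized; prediction is
  argmax with ties broken toward the first declared class, documented for
  reproducibility.
* The **empty mask is legal** and yields the prior-only classifier. The
  optimizers can and do generate the all-zeros mask; penalizing it
  arbitrarily would distort the fitness landscape, so it simply scores near
  the majority-class rate.

`cv_fitness()` is a pure function of `(ds, mask, k, seed)`; fold membership
and model fitting consume no ambient RNG. This purity is what makes the
evaluator cache in `make_cv_evaluator()` safe: identical masks recur
constantly in converged populations, so results are memoised by bit-string.

## The genetic algorithm

Population 30, binary encoding, initial bits i.i.d. Bernoulli(0.5) — the
initial number of selected features is free, not fixed. Each generation:

1. the best half (15 masks) survives by fitness, which necessarily includes
   the top-3 elites that persist unconditionally;
2. the other 15 slots are refilled by offspring: two parents drawn by
   roulette wheel over the *full* previous population, one-point crossover,
   bit-flip mutation on both children (an odd surplus child is discarded).

With 30 masks and replacement fraction 0.5 this produces exactly 15 new
solutions per generation: 1,500, 7,500 and 15,000 offspring at 100, 500 and
1,000 generations. The defaults are population 30, mutation rate 0.01,
parent selection rate 0.5. Design points that were genuinely open and the
choices made:

* *Parents from the full population vs. survivors only*: we draw from the
  full evaluated generation (classical roulette). Elites are not exempt
  from being parents.
* *Survivor rule*: best half by fitness. This subsumes the top-3 guarantee
  while matching the half-replacement accounting.
* *Duplicates*: offspring are not deduplicated; the cache makes repeated
  evaluation free.

## Harmony search

Harmony memory size 30, HMCR 0.85, PAR 0.7, binary encoding, one improvised
candidate per iteration. Per bit, with probability HMCR the bit is copied
from a uniformly chosen memory harmony (the source harmony is drawn
independently per bit, the canonical memory-consideration rule); otherwise
it is Bernoulli(0.5). The candidate replaces the worst memory entry only on
a *strict* fitness improvement — ties are rejections.

The binary meaning of pitch adjustment at PAR = 0.7 is genuinely ambiguous,
so both readings are implemented behind `par_mode`:

* `per_harmony` (default): with probability PAR, flip exactly one uniformly
  chosen bit of the candidate. This is the single-pitch-step analogue of
  bit-flip mutation; a per-bit flip at 0.7 would randomize 70% of inherited
  bits and destroy the memory's information, which is inconsistent with the
  convergence these searches exhibit.
* `per_bit`: flip each memory-derived bit independently with probability
  PAR, kept for fidelity experiments.

Neither mode is claimed to be anyone else's exact mechanics; the default is
the one that converges.

## Dynamic parameter schedules

Both optimizers share linear schedules over the run index (0-based, over
`index / (total - 1)` so both endpoints are attained):

| parameter | start | end | direction |
|---|---|---|---|
| HMCR | 0.7 | 1.0 | increasing — explore early, exploit late |
| GA mutation rate | 0.1 | 0.001 | decreasing, floored at 0.001 |

The mutation floor prevents premature convergence; PAR stays fixed because
in binary encoding pitch adjustment *is* mutation, and scheduling it would
double-count the mutation schedule. Interpolation is over the iteration
index rather than elapsed fitness evaluations — with one candidate per HS
iteration and a fixed 15 offspring per GA generation the two are
proportional anyway. Setting a schedule's endpoints equal reproduces the
fixed-parameter run bit for bit under the same seed; this parity is tested
and is the structural precondition for any fixed-vs-dynamic comparison.

## Filter baselines

Information gain is computed on discretized columns (equal-frequency, 10
bins — a deterministic choice, simpler than entropy-minimizing
discretization and adequate for the synthetic surfaces tested; documented
as a dialect difference from other toolkits). The selection threshold of
0.1 bits is inclusive. CFS scores subsets by the Ghiselli merit
`k·r̄_cf / sqrt(k + k(k−1)·r̄_ff)` with symmetrical uncertainty
`2·I(X;Y)/(H(X)+H(Y))` as the correlation, searched by forward best-first
with a stale limit of 5 consecutive non-improving expansions (the common
default for this search). Missing values are excluded pairwise from all
contingency tables.

## Synthetic surveys and what they do (not) show

`generate_survey()` emulates the target data's statistical shape: 6,488
instances, 2,564 positives (39.5%), 778 features, ~80% nominal with 2–6
categories drawn per contiguous 20-feature block (imitating survey
sections), i.i.d. missingness (default 10%, a typical survey item
nonresponse level), and a small informative subset. Informative nominal
features tilt their first category's probability by ±`effect` between
classes; informative numeric features shift the positive-class mean by
`effect` SD units. The default effect of 0.3 is a moderate, detectable
signal: strong enough that information gain separates informative from
noise features at n ≈ 6,500, weak enough that selection is not trivial.

What this generator deliberately does **not** reproduce: real surveys have
correlated items, structured (non-random) missingness, ordinal scales with
meaningful order, and many weakly informative features. Passing the
recovery tests therefore shows the optimizers find planted independent
signal under class imbalance and missingness — not that they would match
any particular published performance on real registration-gated data, which
is out of scope here.

Test problem sizes were chosen to exercise every code path at interactive
speed: oracle-equivalence runs use 10 features and 120 instances (so the
2^10 exhaustive optimum is computable), recovery runs use 50 features,
5 informative, and 2,000 instances.

## Numerical and degenerate-input choices

* Posterior normalization subtracts the row max before exponentiation;
  log-space and direct-product arithmetic agree to 1e-9 on small problems.
* All-zero fitness wheels fall back to uniform parent selection.
* A constant numeric column discretizes to a single bin; symmetrical
  uncertainty of two constant columns is defined as 0; zero-denominator F1
  is defined as 0 (the conventional choice, which fixes the value of the
  all-negative degenerate prediction).
* AUC is the midrank Mann–Whitney statistic on positive-class scores; for
  binary labels the class-weighted one-vs-rest average collapses to this
  single number, so only the binary AUC is reported.
* Wall time in experiment results covers the selection phase only;
  classifier training/scoring is excluded.

## Known limitations

* Naive Bayes assumes conditional independence; with strongly correlated
  survey blocks the wrapper fitness can prefer redundant subsets.
* The equal-frequency discretization and the smoothing/variance-floor
  constants are this package's documented choices; numeric parity with any
  other toolkit's naive Bayes or CFS is not claimed.
* The evaluation classifiers behind `classifier_registry()` (rpart, ranger,
  e1071 SVM) run at their host defaults; the rf/svm adapters complete
  missing cells with training modes/medians internally because those
  learners reject NA — the data model itself never imputes.
* Multi-class labels are formally supported by the metrics but untested;
  the package targets binary diagnosis.
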