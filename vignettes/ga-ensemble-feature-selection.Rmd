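---
title: "Two-layer evolutionary feature selection for weighted-vote ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-layer evolutionary feature selection for weighted-vote ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(efsemble)
```

## The problem

Breast-cancer-related lymphedema — chronic limb swelling after node
dissection, surgery or radiotherapy — can be managed far better when the
patients at risk are identified early. The data available for that task are
clinic registries: one row per patient, a few dozen demographic, clinical
and lymphedema-specific variables of mixed type, a strongly imbalanced
outcome (roughly three cases per control in a referral clinic), and enough
incomplete records that complete-case exclusion is part of the protocol.
`efsemble` implements a two-layer evolutionary method for exactly this kind
of table: a weighted-vote ensemble of heterogeneous classifiers in which a
genetic algorithm *jointly* optimises each classifier's feature subset and
its voting weight.

## The model

### Chromosome

A candidate solution couples two parts:

* `el`, a vector of `R` learner weights, each in `[0, 1]`;
* `fs`, a binary `R x N` matrix whose row `j` selects the features learner
  `j` is trained on.

`R = 5` in the default roster: k-nearest neighbours (`k = 3`), an RBF-kernel
support vector machine, linear discriminant analysis, Gaussian naive Bayes,
and an entropy-split decision tree. Every `fs` row must keep at least one
feature and at least one weight must be positive; search operators that
violate this are *repaired* (one random bit restored, or weights reset to
uniform) rather than rejected, keeping the operators closed over the
feasible space.

The weights are deliberately **not** simplex-constrained: the vote
normalises by their sum, so `el` and `2 * el` encode the same classifier.
The score for a case with hard votes `v_1, ..., v_R` is

    score = sum_j el_j v_j / sum_j el_j  in [0, 1]

and the label is `1` iff `score >= 0.5`. The tie at exactly `0.5` goes to
the positive (lymphedema) class; this convention is a design choice — a
missed case is clinically costlier than a false alarm, and the midpoint of
the normalised score is the only symmetric threshold.

### Fitness

A chromosome is scored by stratified k-fold cross-validation (default
`K = 10`, the value at which the reference protocol reports peak
efficiency). In each fold the five learners are refitted on the training
part under their masks and the ensemble is applied to the held-out part.
Errors are decomposed biometric-style with the *healthy* class (label 0) as
the target class:

* `FPR` — false acceptance rate: lymphedema cases accepted as healthy;
* `FRR` — false rejection rate: healthy cases flagged as lymphedema;
* `err` — overall misclassification rate.

The scalar cost is `w_err * err + w_fpr * FPR + w_frr * FRR`, by default
with equal weights `(1/3, 1/3, 1/3)`; the weights are fully configurable
(`cost_weights()`), since their reference values are not published — a
clinician who fears missed cases more than false alarms sets
`w_fpr < w_frr`. Fitness is `1 / max(cost, 1e-6)`; the floor keeps fitness
finite on separable folds.

Per-fold costs are averaged by default (`fold_aggregation = "mean"`); a
`"pooled"` mode that sums confusion counts over folds before computing one
cost is provided because published confusion matrices of this protocol
appear pooled. Folds are stratified — with a 3:1 imbalance, unstratified
folds can lose the minority class entirely.

### Search

Per generation, with population 50 (default):

* the best `p_elite = 10%` chromosomes transfer unchanged (elitism — the
  best cost per generation is therefore non-increasing);
* `p_crossover = 60%` are children: feature bits mix uniformly between two
  parents, weights blend convexly with a shared `beta ~ U(0, 1)`;
* the remaining `p_mutation = 30%` are mutants: each bit flips with
  probability `1/N` (the classical rate — one expected flip per learner
  row), weights perturbed by clipped Gaussian noise (`sd = 0.1`).

Parents are drawn by roulette-wheel selection with power 2: chromosome `i`
is chosen with probability `fitness_i^2 / sum_j fitness_j^2`. Termination
is the iteration count alone (default 100). Two share presets are shipped —
`"table1"` (0.10/0.60/0.30, the default) and `"prose"` (0.10/0.50/0.40) —
because both triples are in circulation for this protocol; they differ only
in the mutation/crossover balance and we found no practical difference on
synthetic cohorts.

The crossover and mutation operator *forms* (uniform bit mixing, convex
weight blend, bit flip, Gaussian perturbation) are our choices: the
reference protocol names the operators but not their forms, and these are
the standard forms that are closed over the chromosome space.

### Reproducibility and caching

A run is a pure function of `(seed, config, data)`; two runs with the same
seed are bitwise identical. Base-learner votes depend only on the learner,
its mask and the fold split — never on `el` — so fold predictions are
memoised per `(learner, mask)` within a run. `vote_cache()` lets repeated
runs on identical data and folds share that memo; results are unchanged.

## Feature-impact ranking

Because the search is stochastic, a single run's selected features are
noisy. The impact pipeline repeats the whole search (30 times by default,
per the reference protocol) and averages selection into a per-feature
percentage. The averaging unit is genuinely ambiguous in the source
protocol, so three modes are exposed:

* `per_slot` (default): share of (run x learner) cells selecting the
  feature — the finest unit and the one whose percentages are least
  saturated;
* `any_learner`: share of runs where any learner selects it;
* `weight_weighted`: weight-normalised selection share per run, averaged.

The alignment coding-flip experiment (`coding_flip_experiment()`) repeats
the pipeline once per coding of the dominant-hand/involved-side alignment
variable (aligned = 0 versus aligned = 1), sharing seeds across arms so the
comparison is paired.

## Preprocessing recipes

`derive_features()` adds age at diagnosis (floor of years between birth and
diagnosis dates), BMI (replacing height and weight; centimetre heights are
detected by magnitude and converted), and the involved/removed lymph-node
ratio; birth and referral dates are dropped. A removed-node count of zero
leaves the ratio *missing* rather than zero or infinite — inventing a value
there would fabricate signal — and such rows fall to complete-case
exclusion. Labels are `1` iff edema volume strictly exceeds 200 mL, so a
volume of exactly 200 mL is class 0. Categorical features are
integer-coded with lexicographic level order, recorded in a sidecar for
inversion.

`finalize_features(balance_factor = 3)` replicates the minority class. The
reference protocol never states balancing, but every published confusion
matrix of it sums to class totals of exactly `690 = 3 x 230` and `740`;
replication is the simplest mechanism consistent with those totals, so it
is shipped as an explicit, default-off step.

## The synthetic cohort generator

No public dataset exists for this protocol, so `simulate_cohort()` draws
lymphedema-like cohorts with known ground truth: 740 cases / 230 controls
by default; age, BMI and node-count marginals matched to the published
descriptive statistics (age 50.19 +/- 11.12 vs 48.0 +/- 10.75, BMI 28.95 vs
27.36, involved nodes 4.09 vs 2.05); edema volume drawn from
class-conditional lognormal tails of the 200 mL rule so volume labelling
reproduces the class exactly; and a clinical feature block cycling
continuous/binary/ordinal kinds with a planted informative subset
(standardised shift `effect_size = 1` by default — a strong but realistic
single-variable effect for clinical tables). Missingness is MCAR: the real
exclusion mechanism is unknown, and MCAR keeps exclusion tests unbiased.

What the generator does *not* emulate: correlated predictors, informative
missingness, measurement error in volumes, or the joint distribution of the
published cohort. Passing tests on these cohorts certify the machinery —
optimisation, ranking, bookkeeping — not clinical validity on real
registries.

## Numerical choices

* SVM features are standardised inside the adapter (training-set mean/sd);
  the solver tolerance is 0.01.
* Naive Bayes uses Gaussian likelihoods with the standard deviation floored
  at `1e-9`; prediction ties go to the lower label.
* KNN vote ties (possible with even `k`) go to the lower label, making
  predictions deterministic.
* LDA on a degenerate training subset (no varying column, collinearity
  failure) falls back to a majority-class constant predictor, recorded on
  the fitted object, rather than aborting a long search.
* "C5"-style trees are implemented with `rpart` splitting on information
  (entropy) gain; this is C4.5-family behaviour except that `rpart` uses
  information gain rather than gain ratio.
* The MLP (one hidden layer, 16 units) participates only in the
  single-learner benchmark, not the five-learner ensemble.

## Problem sizes used by the tests and the acceptance script

The shipped checks run on one CPU in minutes: the paired
baseline-versus-optimised comparison uses a 970-row cohort (30 features, 6
informative) with population 20, 20 generations and 5-fold fitness; the
exhaustive-enumeration certificate uses 6 features x 2 learners on 60 rows
(63^2 mask combinations); the impact-recovery experiment uses 300-row
cohorts with 10 repeat runs at population 8, 6 generations, 3-fold fitness.
These are the package's chosen demonstration scales; the full protocol
(population 50, 100 generations, 10 folds, 30 repeats) is the default
configuration and simply takes proportionally longer.

## Known limitations

* The optimised chromosome's reported cost inherits selection bias: it is
  chosen as the minimum over all evaluated chromosomes of the same
  cross-validated surface it is reported on. The paired direction against
  the equal-weight baseline on shared folds is the meaningful readout; an
  unbiased absolute estimate would need nested cross-validation, which the
  reference protocol does not perform.
* Hard 0/1 votes only; no probability calibration, ROC analysis or
  class-prior-adjusted thresholds.
* No imputation: incomplete records are excluded, as in the source
  protocol.
* Minority replication changes apparent class priors for every learner;
  it reconstructs the published evaluation regime and is not a general
  recommendation for handling imbalance.
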